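#' Read and write mixture specifications as JSON
#'
#' Two spec layouts are supported. Discrete:
#' `{"type":"discrete","weights":[...],"distributions":[[...],...]}`.
#' Gaussian:
#' `{"type":"gaussian","components":[{"weight":w,"mean":[...],"cov":[[...]]},...]}`,
#' where a univariate component may use the shorthand
#' `{"weight":w,"mean":m,"sd":s}`. All construction invariants (weight and
#' row normalization, covariance positive definiteness) are re-validated on
#' read, so a spec that was edited by hand fails loudly rather than silently.
#'
#' @param path file path of the JSON spec.
#' @return `read_mixture()` returns a [discrete_mixture()] or
#'   [gaussian_mixture()].
#' @export
read_mixture <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  mixture_from_spec(spec)
}

#' @param spec a list with the structure of the JSON layouts above (already
#'   parsed); useful when specs are assembled programmatically.
#' @rdname read_mixture
#' @export
mixture_from_spec <- function(spec) {
  type <- spec$type
  if (is.null(type)) stop("mixture spec needs a 'type' field", call. = FALSE)
  if (type == "discrete") {
    P <- do.call(rbind, lapply(spec$distributions, unlist))
    return(discrete_mixture(unlist(spec$weights), P))
  }
  if (type == "gaussian") {
    comps <- lapply(spec$components, function(cs) {
      if (!is.null(cs$sd)) {
        if (length(unlist(cs$mean)) != 1L) {
          stop("'sd' shorthand is only valid for univariate components",
               call. = FALSE)
        }
        gaussian_component(unlist(cs$mean), unlist(cs$sd)^2)
      } else {
        gaussian_component(unlist(cs$mean),
                           do.call(rbind, lapply(cs$cov, unlist)))
      }
    })
    w <- vapply(spec$components, function(cs) as.numeric(cs$weight), numeric(1))
    return(gaussian_mixture(comps, w))
  }
  stop(sprintf("unknown mixture type '%s'", type), call. = FALSE)
}

#' @param mix a mixture to serialize.
#' @return `write_mixture()` invisibly returns `path`.
#' @rdname read_mixture
#' @export
write_mixture <- function(mix, path) {
  spec <- if (inherits(mix, "discrete_mixture")) {
    list(type = "discrete",
         weights = mix$weights,
         distributions = lapply(seq_len(nrow(mix$distributions)),
                                function(i) mix$distributions[i, ]))
  } else if (inherits(mix, "gaussian_mixture")) {
    list(type = "gaussian",
         components = lapply(seq_along(mix$weights), function(i) {
           cc <- mix$components[[i]]
           list(weight = mix$weights[i], mean = cc$mean,
                cov = lapply(seq_len(cc$n), function(r) cc$cov[r, ]))
         }))
  } else {
    stop("'mix' must be a discrete_mixture or gaussian_mixture", call. = FALSE)
  }
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
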