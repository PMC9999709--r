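#' Get a scalar from a nested parameter list by slash-path
#'
#' Parameter paths address any scalar inside a [ModelParameters] object,
#' e.g. `"utilities/u_chd_year1"` or `"treatments/statin/rr_chd"`. Used by
#' the one-way sensitivity analysis and the PSA so that any parameter can
#' be varied without bespoke code.
#'
#' @param params a nested list (typically `irapen_params`)
#' @param path slash-separated path to a scalar
#' @return the scalar value at `path`
#' @export
param_get <- function(params, path) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop("parameter path not found: ", path, call. = FALSE)
    }
    node <- node[[k]]
  }
  if (is.list(node) || length(node) != 1) {
    stop("parameter path does not address a scalar: ", path, call. = FALSE)
  }
  node
}

#' Set a scalar in a nested parameter list by slash-path
#'
#' @inheritParams param_get
#' @param value replacement scalar
#' @return the modified list
#' @export
param_set <- function(params, path, value) {
  if (!is.numeric(value) && !is.logical(value)) {
    stop("param_set only handles numeric/logical scalars", call. = FALSE)
  }
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  current <- param_get(params, path)  # validates the path addresses a scalar
  if (!is.numeric(current) && !is.logical(current)) {
    stop("parameter path does not address a numeric scalar: ", path, call. = FALSE)
  }
  rec <- function(node, ks) {
    if (length(ks) == 1L) {
      node[[ks]] <- value
      return(node)
    }
    node[[ks[1L]]] <- rec(node[[ks[1L]]], ks[-1L])
    node
  }
  rec(params, keys)
}

# deterministic 31-bit string hash (polynomial rolling); used to derive
# per-parameter RNG substreams so adding a parameter never perturbs the
# draws of the others
.string_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

.substream_seed <- function(seed, path) {
  as.integer((as.numeric(seed) * 48271 + .string_hash(path)) %% 2147483647)
}

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
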