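#' @useDynLib crmbattery, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rnorm rpois runif
#' @importFrom utils head packageVersion
NULL

# Orientation symbols: canonical ASCII "+"/"-"; U+2212 (as printed in
# the literature) is accepted on input and normalized.
normalize_orientation <- function(x) {
  x <- gsub("−", "-", as.character(x))
  bad <- !x %in% c("+", "-")
  if (any(bad)) {
    stop("invalid orientation value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Oriented key of a binding site
#'
#' The oriented key is the orientation symbol prefixed to the factor
#' name, e.g. `"+ETSF"` or `"-PAX6"`; it is the hash key under which
#' promoter profiles index their sites.
#'
#' @param factor_id character vector of TF family names.
#' @param orientation character vector of `"+"`/`"-"` (U+2212 accepted).
#' @return character vector of oriented keys.
#' @examples
#' oriented_key(c("ETSF", "PAX6"), c("+", "-"))
#' @export
oriented_key <- function(factor_id, orientation) {
  factor_id <- as.character(factor_id)
  if (any(!nzchar(factor_id)) || anyNA(factor_id)) {
    stop("factor_id must be non-empty", call. = FALSE)
  }
  paste0(normalize_orientation(orientation), factor_id)
}

# Split oriented keys back into (factor_id, orientation).
split_oriented_key <- function(key) {
  key <- gsub("−", "-", as.character(key))
  ok <- grepl("^[+-].+", key)
  if (any(!ok)) {
    stop("malformed oriented key(s): ",
         paste(unique(key[!ok]), collapse = ", "), call. = FALSE)
  }
  data.frame(factor_id = substring(key, 2),
             orientation = substring(key, 1, 1),
             stringsAsFactors = FALSE)
}

# Coerce a module-element specification to a character vector of
# oriented keys. Accepts: character keys, a data.frame with
# factor_id/orientation columns, or a list of (factor, orientation)
# pairs.
as_elements <- function(elements) {
  if (is.character(elements)) {
    spl <- split_oriented_key(elements) # validates
    return(oriented_key(spl$factor_id, spl$orientation))
  }
  if (is.data.frame(elements)) {
    stopifnot(all(c("factor_id", "orientation") %in% names(elements)))
    return(oriented_key(elements$factor_id, elements$orientation))
  }
  if (is.list(elements)) {
    return(vapply(elements, function(e) oriented_key(e[[1]], e[[2]]), ""))
  }
  stop("cannot interpret module elements", call. = FALSE)
}

# Locale-independent sort used for all canonical orderings.
sort_c <- function(x) {
  if (!length(x)) return(character())
  sort(x, method = "radix")
}

# Deterministic 31-bit sub-seed derived from a master seed and integer
# tags, so per-(N, rep) streams reproduce regardless of loop order.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 69069 + (as.numeric(t) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
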