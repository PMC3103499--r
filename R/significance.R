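# Statistical significance of common CRMs: hypergeometric upper-tail
# p-value of the battery support count against a background gene set,
# plus the randomized battery-size -> threshold calibration.

#' Hypergeometric upper-tail p-value
#'
#' Probability of observing at least `n` module-carrying genes when
#' drawing `N` genes from a background of `B` genes of which `b` carry
#' the module: `P(X >= n)` for `X ~ Hypergeometric(B, b, N)`. Computed
#' in log space (`lchoose` + log-sum-exp), so it is stable for large
#' backgrounds.
#'
#' @param B background size (genes), `B >= N`.
#' @param b background hits, `0 <= b <= B`.
#' @param N battery size (draws).
#' @param n battery hits, `0 <= n <= min(N, b)`.
#' @return p-value in `[0, 1]`.
#' @examples
#' hypergeom_upper_pvalue(5000, 37, 8, 6)
#' @export
hypergeom_upper_pvalue <- function(B, b, N, n) {
  B <- as.numeric(B); b <- as.numeric(b)
  N <- as.numeric(N); n <- as.numeric(n)
  if (anyNA(c(B, b, N, n)) || b < 0 || b > B || N < 0 || N > B ||
      n < 0 || n > min(N, b)) {
    stop("hypergeometric bounds violated: need 0 <= b <= B, N <= B, ",
         "0 <= n <= min(N, b)", call. = FALSE)
  }
  if (n == 0) return(1.0)
  i <- seq(n, min(N, b))
  logp <- lchoose(b, i) + lchoose(B - b, N - i) - lchoose(B, N)
  m <- max(logp)
  p <- exp(m + log(sum(exp(logp - m))))
  min(max(p, 0), 1)
}

#' Count background genes carrying a module
#'
#' Raw gene-level presence (alternative-promoter heuristic, no length
#' band): the battery-specific length band is not meaningful
#' genome-wide, and presence on any promoter is what the background
#' profiles answer directly.
#'
#' @param elements module elements (oriented keys).
#' @param background list of [gene_profile()] objects or a
#'   [pack_profiles()] result (pack once when scoring many modules).
#' @return integer count `b`.
#' @export
count_background_hits <- function(elements, background) {
  packed <- pack_profiles(background)
  if (!length(packed$gene_ids)) stop("background is empty", call. = FALSE)
  sum(!is.na(packed_min_spans(packed, as_elements(elements))))
}

#' Score a CRM against a background
#'
#' `n` is the band-filtered support count the battery reports
#' (`length(crm$support_genes)`), `b` the raw background presence
#' count; the p-value is the hypergeometric upper tail.
#'
#' @param crm an evaluated [crm][evaluate_module].
#' @inheritParams count_background_hits
#' @return the `crm` with `p_value` filled in.
#' @export
score_crm <- function(crm, background) {
  packed <- pack_profiles(background)
  B <- length(packed$gene_ids)
  b <- count_background_hits(crm$elements, packed)
  n <- length(crm$support_genes)
  # Battery genes need not belong to the background, so the support can
  # exceed the background hit count; P(X >= n) is then an empty tail
  # sum and the p-value is exactly 0.
  n_eff <- min(n, crm$n_battery)
  crm$p_value <- if (n_eff > b) 0 else {
    hypergeom_upper_pvalue(B, b, crm$n_battery, n_eff)
  }
  crm
}

#' @rdname score_crm
#' @param crms a `crm_set`.
#' @export
score_crms <- function(crms, background) {
  packed <- pack_profiles(background)
  out <- lapply(crms, score_crm, background = packed)
  structure(out, class = c("crm_set", "list"))
}

#' Calibrate battery-size-dependent significance thresholds
#'
#' For each battery size N the procedure draws `reps` random batteries
#' of N genes (without replacement) from the background, runs the full
#' common-CRM search on each, scores every common CRM against the same
#' background, and records the minimum p-value of the draw (1.0 when no
#' common CRM is found — conservative, and it keeps reps comparable).
#' The threshold for size N is the mean of the recorded minima; for
#' `N >= floor_size` the entry is replaced by the single floor
#' threshold (default 0.01). Per-(N, rep) RNG substreams are derived
#' deterministically from `seed`, so results do not depend on loop
#' order.
#'
#' @inheritParams count_background_hits
#' @param sizes battery sizes to calibrate (default 4..20).
#' @param reps random batteries per size (default 100).
#' @param config a [search_config()]; its `delta` is the calibration
#'   delta.
#' @param seed master seed (mandatory for reproducibility).
#' @param floor_size,floor_threshold sizes from `floor_size` up use the
#'   fixed `floor_threshold` (defaults 14 and 0.01).
#' @return object of class `calibration_table`: data.frame with columns
#'   N, threshold, raw_mean, plus attributes reps, delta, seed,
#'   floor_size, floor_threshold.
#' @export
calibrate_thresholds <- function(background, sizes = 4:20, reps = 100L,
                                 config = search_config(), seed,
                                 floor_size = 14L, floor_threshold = 0.01) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  packed <- pack_profiles(background)
  genes_by_id <- NULL
  if (!inherits(background, "packed_profiles")) {
    genes_by_id <- background
    names(genes_by_id) <- vapply(background, function(g) g$gene_id, "")
  } else {
    stop("calibrate_thresholds needs the gene profile list (it must ",
         "subset genes), not a packed object", call. = FALSE)
  }
  B <- length(packed$gene_ids)
  stopifnot(reps >= 1, all(sizes >= 2))
  if (any(sizes > B)) stop("battery size exceeds background size B = ", B,
                           call. = FALSE)
  raw_mean <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    N <- sizes[si]
    minima <- numeric(reps)
    for (r in seq_len(reps)) {
      set.seed(derive_seed(seed, N, r))
      draw <- sample(names(genes_by_id), N)
      crms <- search_common_crms(genes_by_id[draw], config)
      if (!length(crms)) {
        minima[r] <- 1.0
      } else {
        scored <- score_crms(crms, packed)
        minima[r] <- min(vapply(scored, `[[`, 1, "p_value"))
      }
    }
    raw_mean[si] <- mean(minima)
  }
  threshold <- ifelse(sizes >= floor_size, floor_threshold, raw_mean)
  tab <- data.frame(N = as.integer(sizes), threshold = threshold,
                    raw_mean = raw_mean)
  structure(tab, class = c("calibration_table", "data.frame"),
            reps = as.integer(reps), delta = config$delta,
            seed = as.integer(seed), floor_size = as.integer(floor_size),
            floor_threshold = floor_threshold)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("<calibration_table> sizes ", min(x$N), "..", max(x$N), ", reps ",
      attr(x, "reps"), ", delta ", attr(x, "delta"), ", seed ",
      attr(x, "seed"), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read / write a calibration table TSV
#'
#' The file carries reps, delta, seed, floor_size and floor_threshold
#' in `#`-prefixed header comments followed by tab-separated columns N,
#' threshold, raw_mean; the reader restores the attributes.
#'
#' @param table a [calibrate_thresholds()] result.
#' @param path file path.
#' @export
write_calibration <- function(table, path) {
  hdr <- sprintf("# %s=%s",
                 c("reps", "delta", "seed", "floor_size", "floor_threshold"),
                 c(attr(table, "reps"), attr(table, "delta"),
                   attr(table, "seed"), attr(table, "floor_size"),
                   attr(table, "floor_threshold")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("N", "threshold", "raw_mean"), collapse = "\t"), con)
  writeLines(sprintf("%d\t%.17g\t%.17g", table$N, table$threshold,
                     table$raw_mean), con)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE))
  meta <- stats::setNames(as.list(kv[, 2]), kv[, 1])
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            stringsAsFactors = FALSE)
  structure(body, class = c("calibration_table", "data.frame"),
            reps = as.integer(meta$reps), delta = as.numeric(meta$delta),
            seed = as.integer(meta$seed),
            floor_size = as.integer(meta$floor_size),
            floor_threshold = as.numeric(meta$floor_threshold))
}

#' Filter CRMs by significance
#'
#' Strict less-than filter of scored CRMs against the battery-size
#' threshold from a calibration table, or against a fixed alpha (the
#' classical single-threshold variant, e.g. `1e-4`).
#'
#' @param crms a scored `crm_set` (see [score_crms()]).
#' @param N battery size used to look up the threshold.
#' @param thresholds a [calibration_table][calibrate_thresholds]
#'   (optional when `alpha` is given).
#' @param alpha fixed significance level overriding the table.
#' @return `crm_set` of CRMs with `p_value < threshold`, ordered by
#'   ascending p-value then label.
#' @export
select_significant <- function(crms, N, thresholds = NULL, alpha = NULL) {
  if (is.null(alpha)) {
    if (is.null(thresholds)) {
      stop("supply a calibration table or a fixed alpha", call. = FALSE)
    }
    i <- match(N, thresholds$N)
    if (is.na(i)) {
      stop("no calibrated threshold for battery size ", N,
           "; run calibrate_thresholds() over this size or supply alpha",
           call. = FALSE)
    }
    alpha <- thresholds$threshold[i]
  }
  p <- vapply(crms, `[[`, 1, "p_value")
  if (anyNA(p)) stop("CRMs must be scored before filtering", call. = FALSE)
  keep <- which(p < alpha)
  out <- crms[keep][order(p[keep], vapply(crms[keep], `[[`, "", "label"),
                          method = "radix")]
  structure(out, class = c("crm_set", "list"))
}
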