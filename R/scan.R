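# Optional sequence front-end: a simple log-odds PWM scanner that
# turns FASTA promoter sequences into a binding-site table. This is a
# generic stand-in for matrix-library scanners; it is not a motif
# model of any particular database.

#' Read position weight matrices
#'
#' Plain-text format: one block per matrix, a header line
#' `>FACTOR_ID <threshold>` followed by four whitespace-separated rows
#' of per-position base probabilities in A, C, G, T order (equal
#' length, each column summing to ~1).
#'
#' @param path file path.
#' @return list of `pwm` objects: factor_id, matrix (4 x width, rows
#'   ACGT), threshold (log2 log-odds score cutoff).
#' @export
read_pwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  out <- list()
  for (i in seq_along(heads)) {
    h <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1L]]
    id <- h[1L]
    thr <- if (length(h) > 1L) as.numeric(h[2L]) else NA_real_
    rows <- lines[(heads[i] + 1L):(heads[i] + 4L)]
    m <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(r, "\\s+")[[1L]])
    }))
    if (nrow(m) != 4L || anyNA(m) || ncol(m) < 1L) {
      stop("malformed PWM block for '", id, "'", call. = FALSE)
    }
    rownames(m) <- c("A", "C", "G", "T")
    out[[id]] <- structure(list(factor_id = id, matrix = m,
                                threshold = thr), class = "pwm")
  }
  out
}

# log2 log-odds weights of a probability matrix against a base
# composition, with a small pseudo-probability guard.
pwm_weights <- function(pwm, bg) {
  eps <- 1e-4
  log2((pwm$matrix + eps) / (bg + eps))
}

#' Scan promoter sequences for PWM matches
#'
#' Scores every window of every sequence on both strands with log2
#' log-odds weights against a base composition (uniform by default) and
#' emits windows scoring at or above the threshold as binding-site
#' records. Reverse-strand matches are reported with orientation `-`
#' at their forward-axis coordinates. Windows containing non-ACGT
#' characters are skipped with a warning.
#'
#' FASTA headers follow `>promoter_id gene_id=<g> offset=<o>` where
#' `offset` is the TSS-relative coordinate of the sequence's first base
#' (default -500, the default promoter region).
#'
#' @param fasta path to a FASTA file, or a named character vector of
#'   sequences (names as the header convention above).
#' @param pwms list from [read_pwms()].
#' @param threshold optional global score cutoff overriding each PWM's
#'   own threshold.
#' @param background length-4 base composition (A, C, G, T), default
#'   uniform.
#' @return site table (gene_id, promoter_id, factor_id, start, end,
#'   orientation) plus a `score` column.
#' @export
scan_sequences <- function(fasta, pwms, threshold = NULL,
                           background = rep(0.25, 4)) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L &&
              file.exists(fasta)) read_fasta(fasta) else fasta
  stopifnot(!is.null(names(seqs)))
  background <- background / sum(background)
  rows <- list()
  for (nm in names(seqs)) {
    h <- strsplit(nm, "\\s+")[[1L]]
    pid <- h[1L]
    kv <- strsplit(grep("=", h[-1L], value = TRUE), "=", fixed = TRUE)
    meta <- stats::setNames(vapply(kv, `[`, "", 2L),
                            vapply(kv, `[`, "", 1L))
    gid <- meta["gene_id"] %|NA|% pid
    offset <- as.integer(meta["offset"] %|NA|% "-500")
    chars <- strsplit(toupper(seqs[[nm]]), "")[[1L]]
    bad <- !chars %in% c("A", "C", "G", "T")
    if (any(bad)) {
      warning("sequence '", pid, "': ", sum(bad),
              " non-ACGT position(s) skipped", call. = FALSE)
    }
    L <- length(chars)
    for (pwm in pwms) {
      W <- ncol(pwm$matrix)
      if (W > L) next
      thr <- threshold %||% pwm$threshold
      if (is.na(thr)) {
        stop("PWM '", pwm$factor_id, "' has no threshold and no global ",
             "threshold was given", call. = FALSE)
      }
      wt <- pwm_weights(pwm, background)
      base_idx <- match(chars, c("A", "C", "G", "T"))
      for (s in seq_len(L - W + 1L)) {
        idx <- base_idx[s:(s + W - 1L)]
        if (anyNA(idx)) next
        fwd <- sum(wt[cbind(idx, seq_len(W))])
        # reverse strand: reverse-complemented window, forward weights
        rev <- sum(wt[cbind(5L - rev(idx), seq_len(W))])
        if (fwd >= thr) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = gid, promoter_id = pid, factor_id = pwm$factor_id,
            start = offset + s - 1L, end = offset + s + W - 2L,
            orientation = "+", score = fwd, stringsAsFactors = FALSE)
        }
        if (rev >= thr) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = gid, promoter_id = pid, factor_id = pwm$factor_id,
            start = offset + s - 1L, end = offset + s + W - 2L,
            orientation = "-", score = rev, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), promoter_id = character(),
                      factor_id = character(), start = integer(),
                      end = integer(), orientation = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# NA-aware default operator for scalar metadata lookups.
`%|NA|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a

# Minimal FASTA reader used when Biostrings is not installed; with
# Biostrings available it is delegated there.
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(as.character(x), names(x)))
  }
  lines <- readLines(path)
  heads <- grep("^>", lines)
  stopifnot(length(heads) >= 1L)
  ends <- c(heads[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(heads), function(i) {
    paste(lines[(heads[i] + 1L):ends[i]], collapse = "")
  }, "")
  stats::setNames(seqs, sub("^>\\s*", "", lines[heads]))
}
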