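# Gene batteries: intersections of temporal expression patterns with
# pathways significantly enriched in them. A battery (pattern x
# pathway overlap) is the unit on which the CRM search runs.

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids.
#'
#' @param path file path.
#' @return named list of character vectors of gene ids; the
#'   `description` attribute of each element holds the second field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("malformed GMT record (need name, description, >=1 member): ",
           substr(ln, 1, 60), call. = FALSE)
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- f[2L]
    out[[f[1L]]] <- members
  }
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors (as from `read_gmt`).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write expression-pattern assignments
#'
#' Two-column TSV with header `gene_id`, `pattern` mapping each gene to
#' its temporal expression pattern label (e.g. early-up, middle-up,
#' late-up, down).
#'
#' @param path file path.
#' @return named list of character vectors: pattern label -> gene ids.
#' @export
read_pattern_assignments <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  stopifnot(all(c("gene_id", "pattern") %in% names(df)))
  split(as.character(df$gene_id), as.character(df$pattern))
}

#' @rdname read_pattern_assignments
#' @param patterns named list: pattern label -> gene ids.
#' @export
write_pattern_assignments <- function(patterns, path) {
  df <- data.frame(
    gene_id = unlist(patterns, use.names = FALSE),
    pattern = rep(names(patterns), lengths(patterns)),
    stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Pathway over-representation in an expression pattern
#'
#' Hypergeometric upper-tail test of each pathway's overlap with the
#' pattern's genes against a gene universe: population `B = |universe|`,
#' successes `b = |pathway n universe|`, draws `N = |pattern|`, hits
#' `n = |pattern n pathway|`. Pathways with no universe overlap are
#' skipped with a message.
#'
#' @param pattern_genes character vector of the pattern's gene ids
#'   (must all be in `universe`).
#' @param pathways named list of pathway gene-id vectors (see
#'   [read_gmt()]).
#' @param universe character vector of all candidate gene ids.
#' @return data.frame with columns pathway, overlap, pathway_size,
#'   pattern_size, universe_size, p_value, plus `genes`
#'   (comma-separated overlap ids), sorted by ascending p-value.
#' @export
pathway_enrichment <- function(pattern_genes, pathways, universe) {
  pattern_genes <- unique(as.character(pattern_genes))
  universe <- unique(as.character(universe))
  out_of_universe <- setdiff(pattern_genes, universe)
  if (length(out_of_universe)) {
    stop("pattern gene(s) outside the universe: ",
         paste(head(out_of_universe, 5), collapse = ", "), call. = FALSE)
  }
  B <- length(universe)
  N <- length(pattern_genes)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(as.character(pathways[[nm]])), universe)
    if (!length(pw)) {
      message("pathway '", nm, "' has no universe overlap; skipped")
      return(NULL)
    }
    ov <- sort_c(intersect(pattern_genes, pw))
    data.frame(pathway = nm, overlap = length(ov),
               pathway_size = length(pw), pattern_size = N,
               universe_size = B,
               p_value = hypergeom_upper_pvalue(B, length(pw), N,
                                                length(ov)),
               genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(pathway = character(), overlap = integer(),
                      pathway_size = integer(), pattern_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$p_value, out$pathway, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build gene batteries from patterns and pathways
#'
#' For every (pattern, pathway) pair whose enrichment p-value is below
#' `alpha` (strict), the overlap gene set becomes a battery. An
#' optional curated pathway allowlist stands in for literature-based
#' pathway selection. Batteries smaller than `min_size` are dropped
#' with a warning (the calibration range starts at 4 genes).
#'
#' @param patterns named list: pattern label -> gene ids.
#' @param pathways named list: pathway name -> gene ids.
#' @param universe gene universe for the enrichment test.
#' @param alpha enrichment significance level (default 0.05).
#' @param allowlist optional character vector of pathway names to keep.
#' @param min_size minimum battery size (default 4).
#' @return list of `battery` objects: battery_id, pattern, pathway,
#'   genes, size, enrichment_p.
#' @export
build_batteries <- function(patterns, pathways, universe, alpha = 0.05,
                            allowlist = NULL, min_size = 4L) {
  if (!is.null(allowlist)) pathways <- pathways[names(pathways) %in% allowlist]
  out <- list()
  for (pat in names(patterns)) {
    enr <- pathway_enrichment(patterns[[pat]], pathways, universe)
    hits <- enr[enr$p_value < alpha, , drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      genes <- strsplit(hits$genes[i], ",", fixed = TRUE)[[1L]]
      if (length(genes) < min_size) {
        warning("battery ", pat, " x ", hits$pathway[i], " has ",
                length(genes), " genes (< ", min_size, "); dropped",
                call. = FALSE)
        next
      }
      id <- paste(pat, hits$pathway[i], sep = "|")
      out[[id]] <- structure(list(battery_id = id, pattern = pat,
                                  pathway = hits$pathway[i],
                                  genes = genes, size = length(genes),
                                  enrichment_p = hits$p_value[i]),
                             class = "battery")
    }
  }
  out[sort_c(names(out))]
}

#' @export
print.battery <- function(x, ...) {
  cat("<battery> ", x$battery_id, ": ", x$size, " genes, enrichment p = ",
      signif(x$enrichment_p, 3), "\n", sep = "")
  invisible(x)
}

#' Write a battery table TSV
#'
#' @param batteries list of batteries from [build_batteries()].
#' @param path output file.
#' @export
write_batteries <- function(batteries, path) {
  df <- data.frame(
    battery_id = vapply(batteries, `[[`, "", "battery_id"),
    pattern = vapply(batteries, `[[`, "", "pattern"),
    pathway = vapply(batteries, `[[`, "", "pathway"),
    size = vapply(batteries, `[[`, 1L, "size"),
    enrichment_p = vapply(batteries, `[[`, 1, "enrichment_p"),
    genes = vapply(batteries, function(b) paste(b$genes, collapse = ","),
                   ""),
    stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
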