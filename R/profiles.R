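# Promoter profiles: a promoter is represented not as sequence but as
# its position-sorted list of oriented TF-family binding sites, with an
# index from oriented key ("+ETSF") to the site start positions. All
# coordinates are integers relative to the TSS (negative = upstream),
# inclusive [start, end]; the default extracted region is -500..+100.

#' Construct a binding-site table
#'
#' Validates and normalizes a set of binding-site records. Each site is
#' an oriented TF-family match with an inclusive TSS-relative extent.
#'
#' @param factor_id TF family names (non-empty strings, e.g. `"NFKB"`).
#' @param start,end integer positions relative to the TSS (negative =
#'   upstream), inclusive; `end >= start` is required. If `end` is
#'   missing a nominal site width is applied.
#' @param orientation `"+"` or `"-"` binding orientation per site.
#' @param width nominal site width in bp used when `end` is missing
#'   (default 12).
#' @return data.frame with columns factor_id, start, end, orientation.
#' @examples
#' binding_sites("ETSF", c(-386, -373), c(-374, -361), "+")
#' @export
binding_sites <- function(factor_id, start, end = NULL, orientation = "+",
                          width = 12L) {
  factor_id <- as.character(factor_id)
  start <- as.integer(start)
  if (is.null(end)) end <- start + as.integer(width) - 1L
  end <- as.integer(end)
  n <- max(length(factor_id), length(start), length(end), length(orientation))
  df <- data.frame(factor_id = rep_len(factor_id, n),
                   start = rep_len(start, n),
                   end = rep_len(end, n),
                   orientation = rep_len(normalize_orientation(orientation), n),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$factor_id)) || anyNA(df$factor_id)) {
    stop("factor_id must be non-empty", call. = FALSE)
  }
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("site coordinates must be integers", call. = FALSE)
  }
  df
}

#' Build a promoter profile
#'
#' Sorts the sites by position, drops exact duplicate records, and
#' builds the oriented-key index mapping each key (orientation + factor
#' name) to the sorted start positions of its sites.
#'
#' @param gene_id,promoter_id identifiers; the promoter belongs to the
#'   gene and `promoter_id` must be unique within it.
#' @param sites a data.frame as returned by [binding_sites()] (columns
#'   factor_id, start, end, orientation); may be unsorted and contain
#'   duplicates. Zero rows give an empty profile.
#' @return an object of class `promoter_profile` with fields `gene_id`,
#'   `promoter_id`, `sites` (sorted data.frame with a `key` column) and
#'   `index` (named list: oriented key -> integer start positions).
#' @examples
#' p <- build_promoter_profile("g1", "g1.p1",
#'   binding_sites("ETSF", c(-373, -386), c(-361, -374), "+"))
#' p$index
#' @export
build_promoter_profile <- function(gene_id, promoter_id, sites) {
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- binding_sites(character(), integer(), integer(), character())
  } else {
    sites <- binding_sites(sites$factor_id, sites$start, sites$end,
                           sites$orientation)
  }
  bad <- sites$end < sites$start
  if (any(bad)) {
    stop("malformed site record(s) with end < start on promoter '",
         promoter_id, "'", call. = FALSE)
  }
  sites$key <- if (nrow(sites)) {
    oriented_key(sites$factor_id, sites$orientation)
  } else character()
  sites <- unique(sites)
  o <- order(sites$start, sites$end, sites$key, method = "radix")
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  index <- lapply(split(sites$start, sites$key), as.integer)
  index <- index[sort_c(names(index))]
  structure(list(gene_id = as.character(gene_id),
                 promoter_id = as.character(promoter_id),
                 sites = sites, index = index),
            class = "promoter_profile")
}

#' @export
print.promoter_profile <- function(x, ...) {
  cat("<promoter_profile> ", x$promoter_id, " (gene ", x$gene_id, "): ",
      nrow(x$sites), " sites, ", length(x$index), " oriented keys\n",
      sep = "")
  invisible(x)
}

#' Build a gene profile from its alternative promoters
#'
#' @param gene_id gene identifier.
#' @param promoters list of [promoter_profile][build_promoter_profile]
#'   objects, all carrying this `gene_id`, with unique promoter ids.
#' @return object of class `gene_profile`.
#' @export
gene_profile <- function(gene_id, promoters) {
  gene_id <- as.character(gene_id)
  stopifnot(length(promoters) >= 1L)
  ids <- vapply(promoters, function(p) p$promoter_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate promoter_id within gene '", gene_id, "'", call. = FALSE)
  }
  owner <- vapply(promoters, function(p) p$gene_id, "")
  if (any(owner != gene_id)) {
    stop("promoter gene_id mismatch for gene '", gene_id, "'", call. = FALSE)
  }
  promoters <- promoters[order(ids, method = "radix")]
  names(promoters) <- sort_c(ids)
  structure(list(gene_id = gene_id, promoters = promoters),
            class = "gene_profile")
}

#' @export
print.gene_profile <- function(x, ...) {
  cat("<gene_profile> ", x$gene_id, ": ", length(x$promoters),
      " promoter(s)\n", sep = "")
  invisible(x)
}

#' Test whether a promoter carries an oriented site
#'
#' A constant-time lookup in the profile's oriented-key index.
#'
#' @param profile a [promoter_profile][build_promoter_profile].
#' @param key oriented key, e.g. `"+ETSF"`.
#' @return `TRUE` iff at least one site matches factor and orientation.
#' @export
has_oriented_site <- function(profile, key) {
  key <- as_elements(key)
  stopifnot(length(key) == 1L)
  !is.null(profile$index[[key]])
}

# Greedy minimal-span matcher on one promoter (reference R
# implementation; the packed C++ kernel must agree with it and both are
# checked against a brute-force oracle in the tests). For each
# candidate first site, picking at every later element the feasible
# site (start > running end) with the smallest end minimizes the final
# end, hence the span for that first site.
match_min_instance <- function(sites, elements) {
  m <- length(elements)
  first_rows <- which(sites$key == elements[1L])
  best <- NULL
  for (i in first_rows) {
    refs <- i
    bound <- sites$end[i]
    ok <- TRUE
    if (m > 1L) {
      for (e in elements[-1L]) {
        cand <- which(sites$key == e & sites$start > bound)
        if (!length(cand)) { ok <- FALSE; break }
        j <- cand[which.min(sites$end[cand])]
        refs <- c(refs, j)
        bound <- sites$end[j]
      }
    }
    if (!ok) next
    span <- bound - sites$start[i] + 1L
    if (is.null(best) || span < best$span ||
        (span == best$span && sites$start[i] < best$first_start)) {
      best <- list(site_refs = refs, span = as.integer(span),
                   first_start = sites$start[i])
    }
  }
  best
}

#' Find a minimum-span module instance on one promoter
#'
#' An instance of an ordered, oriented element sequence is a selection
#' of distinct sites whose oriented keys equal the elements in order,
#' strictly ordered and non-overlapping by position (each site starts
#' after the previous one ends). Among all instances the one with the
#' smallest genomic span (end of last site - start of first site + 1)
#' is returned; ties are broken toward the most-upstream first site.
#'
#' @param profile a [promoter_profile][build_promoter_profile].
#' @param elements ordered module elements: a character vector of
#'   oriented keys (`c("+NFKB", "-CREB")`), or a data.frame with
#'   columns factor_id/orientation.
#' @return `NULL` if no instance exists, else a `crm_instance`: list
#'   with gene_id, promoter_id, site_refs (row indices into
#'   `profile$sites`), span, first_start.
#' @export
find_min_instance <- function(profile, elements) {
  elements <- as_elements(elements)
  if (!length(elements)) stop("elements must be non-empty", call. = FALSE)
  hit <- match_min_instance(profile$sites, elements)
  if (is.null(hit)) return(NULL)
  structure(c(list(gene_id = profile$gene_id,
                   promoter_id = profile$promoter_id), hit),
            class = "crm_instance")
}

#' Gene-level module presence under the alternative-promoter heuristic
#'
#' A module present on any alternative promoter of a gene is treated as
#' present for the gene; the gene-level instance length is the minimum
#' span over all instances on all of its promoters.
#'
#' @param gene a [gene_profile()].
#' @inheritParams find_min_instance
#' @return list with `present` (logical), `span` (integer or `NA`), and
#'   `instance` (the minimal `crm_instance` or `NULL`). Ties on span are
#'   broken by most-upstream first site, then lexicographic promoter id.
#' @export
gene_min_instance <- function(gene, elements) {
  elements <- as_elements(elements)
  best <- NULL
  for (p in gene$promoters) { # already in lexicographic promoter order
    hit <- find_min_instance(p, elements)
    if (is.null(hit)) next
    if (is.null(best) || hit$span < best$span ||
        (hit$span == best$span && hit$first_start < best$first_start)) {
      best <- hit
    }
  }
  if (is.null(best)) {
    list(present = FALSE, span = NA_integer_, instance = NULL)
  } else {
    list(present = TRUE, span = best$span, instance = best)
  }
}

#' Per-gene module presence over a battery
#'
#' Vectorized [gene_min_instance()] preserving gene order.
#'
#' @param genes list of [gene_profile()] objects with unique gene ids.
#' @inheritParams find_min_instance
#' @return data.frame with columns gene_id, present, span.
#' @export
battery_presence_vector <- function(genes, elements) {
  elements <- as_elements(elements)
  ids <- vapply(genes, function(g) g$gene_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in battery", call. = FALSE)
  }
  if (!length(genes)) {
    return(data.frame(gene_id = character(), present = logical(),
                      span = integer(), stringsAsFactors = FALSE))
  }
  res <- lapply(genes, gene_min_instance, elements = elements)
  data.frame(gene_id = ids,
             present = vapply(res, `[[`, TRUE, "present"),
             span = vapply(res, `[[`, 1L, "span"),
             stringsAsFactors = FALSE)
}

# ---- collection construction and round-trip I/O ----------------------

#' Build gene profiles from a site table
#'
#' @param site_table data.frame with columns gene_id, promoter_id,
#'   factor_id, start, end, orientation (see [read_site_table()]).
#' @return named list of [gene_profile()] objects (class
#'   `gene_profile_set`), ordered by gene id.
#' @export
build_gene_profiles <- function(site_table) {
  req <- c("gene_id", "promoter_id", "factor_id", "start", "end",
           "orientation")
  miss <- setdiff(req, names(site_table))
  if (length(miss)) {
    stop("site table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  site_table <- as.data.frame(site_table, stringsAsFactors = FALSE)
  site_table$gene_id <- as.character(site_table$gene_id)
  site_table$promoter_id <- as.character(site_table$promoter_id)
  by_gene <- split(seq_len(nrow(site_table)), site_table$gene_id)
  genes <- list()
  for (gid in sort_c(names(by_gene))) {
    gt <- site_table[by_gene[[gid]], , drop = FALSE]
    by_prom <- split(seq_len(nrow(gt)), gt$promoter_id)
    proms <- lapply(sort_c(names(by_prom)), function(pid) {
      build_promoter_profile(gid, pid, gt[by_prom[[pid]], , drop = FALSE])
    })
    genes[[gid]] <- gene_profile(gid, proms)
  }
  structure(genes, class = c("gene_profile_set", "list"))
}

#' @export
print.gene_profile_set <- function(x, ...) {
  np <- sum(vapply(x, function(g) length(g$promoters), 1L))
  cat("<gene_profile_set> ", length(x), " genes, ", np, " promoters\n",
      sep = "")
  invisible(x)
}

#' Flatten profiles back to a site table
#'
#' Inverse of [build_gene_profiles()]: `build_gene_profiles(
#' as_site_table(x))` reproduces `x`.
#'
#' @param x a promoter_profile, gene_profile, or list of gene profiles.
#' @return data.frame with the canonical site-table columns.
#' @export
as_site_table <- function(x) {
  if (inherits(x, "promoter_profile")) {
    s <- x$sites
    return(data.frame(gene_id = rep(x$gene_id, nrow(s)),
                      promoter_id = rep(x$promoter_id, nrow(s)),
                      factor_id = s$factor_id, start = s$start,
                      end = s$end, orientation = s$orientation,
                      stringsAsFactors = FALSE))
  }
  if (inherits(x, "gene_profile")) {
    return(do.call(rbind, lapply(x$promoters, as_site_table)))
  }
  out <- do.call(rbind, lapply(x, as_site_table))
  rownames(out) <- NULL
  out
}

#' Read / write a TSV site table
#'
#' The on-disk format is tab-separated with header columns `gene_id`,
#' `promoter_id`, `factor_id`, `start`, `end`, `strand` (+/-). All
#' coordinates are TSS-relative signed integers, inclusive intervals.
#' If `end` is absent a nominal width is applied.
#'
#' @param path file path.
#' @param width nominal site width when `end` is missing (default 12).
#' @return data.frame with columns gene_id, promoter_id, factor_id,
#'   start, end, orientation.
#' @export
read_site_table <- function(path, width = 12L) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "gene_id"),
                          data.table = FALSE, showProgress = FALSE)
  if (!"orientation" %in% names(dt) && "strand" %in% names(dt)) {
    dt$orientation <- dt$strand
    dt$strand <- NULL
  }
  req <- c("gene_id", "promoter_id", "factor_id", "start")
  miss <- setdiff(req, names(dt))
  if (length(miss)) {
    stop("site table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"end" %in% names(dt)) dt$end <- dt$start + as.integer(width) - 1L
  dt$gene_id <- as.character(dt$gene_id)
  dt$promoter_id <- as.character(dt$promoter_id)
  dt$factor_id <- as.character(dt$factor_id)
  dt$start <- as.integer(dt$start)
  dt$end <- as.integer(dt$end)
  dt$orientation <- normalize_orientation(dt$orientation)
  dt[, c("gene_id", "promoter_id", "factor_id", "start", "end",
         "orientation")]
}

#' @rdname read_site_table
#' @param x site table or profile object ([as_site_table()] is applied).
#' @export
write_site_table <- function(x, path) {
  if (!is.data.frame(x)) x <- as_site_table(x)
  out <- data.frame(gene_id = x$gene_id, promoter_id = x$promoter_id,
                    factor_id = x$factor_id, start = x$start, end = x$end,
                    strand = x$orientation, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Convert genome-coordinate GFF3 TFBS features to a TSS-relative site table
#'
#' Reads a GFF3 file (1-based, inclusive coordinates per the GFF3
#' standard) whose features of type `TFBS` carry `factor_id`, `gene_id`
#' and `promoter_id` attributes, and converts genome coordinates to
#' TSS-relative signed positions using a promoter TSS table. For a gene
#' on the minus strand the axis is flipped (`rel_start = tss - end`)
#' and site orientation is re-expressed relative to the gene.
#'
#' @param path GFF3 file.
#' @param tss_table data.frame with columns promoter_id, tss (genomic
#'   1-based position), gene_strand (+/-).
#' @return site table as from [read_site_table()].
#' @export
read_site_table_gff3 <- function(path, tss_table) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(f, length, 1L) == 9L
  f <- f[ok]
  m <- do.call(rbind, f)
  keep <- m[, 3] == "TFBS"
  m <- m[keep, , drop = FALSE]
  attr_get <- function(a, k) {
    v <- regmatches(a, regexpr(paste0("(^|;)", k, "=[^;]*"), a))
    sub(paste0("^;?", k, "="), "", v)
  }
  gid <- attr_get(m[, 9], "gene_id")
  pid <- attr_get(m[, 9], "promoter_id")
  fid <- attr_get(m[, 9], "factor_id")
  tss_table <- as.data.frame(tss_table, stringsAsFactors = FALSE)
  i <- match(pid, as.character(tss_table$promoter_id))
  if (anyNA(i)) {
    stop("GFF3 promoter_id(s) missing from tss_table: ",
         paste(unique(pid[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  tss <- as.integer(tss_table$tss[i])
  gstrand <- normalize_orientation(tss_table$gene_strand[i])
  gstart <- as.integer(m[, 4]); gend <- as.integer(m[, 5])
  strand <- normalize_orientation(m[, 7])
  plus <- gstrand == "+"
  rel_start <- ifelse(plus, gstart - tss, tss - gend)
  rel_end <- ifelse(plus, gend - tss, tss - gstart)
  orient <- ifelse(strand == gstrand, "+", "-")
  data.frame(gene_id = gid, promoter_id = pid, factor_id = fid,
             start = as.integer(rel_start), end = as.integer(rel_end),
             orientation = orient, stringsAsFactors = FALSE)
}

# ---- packed representation for the compiled kernels ------------------

#' Pack gene profiles for fast batch instance queries
#'
#' Concatenates all sites of all promoters into flat arrays consumed by
#' the compiled minimal-span kernel. Packing once and reusing the
#' result is what makes module search and background scoring cheap.
#'
#' @param genes list of [gene_profile()] objects (or an already packed
#'   object, returned unchanged).
#' @return object of class `packed_profiles`.
#' @export
pack_profiles <- function(genes) {
  if (inherits(genes, "packed_profiles")) return(genes)
  gene_ids <- vapply(genes, function(g) g$gene_id, "")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_id", call. = FALSE)
  proms <- list(); promo_gene <- integer(); promo_ids <- character()
  for (gi in seq_along(genes)) {
    for (p in genes[[gi]]$promoters) {
      proms[[length(proms) + 1L]] <- p
      promo_gene <- c(promo_gene, gi)
      promo_ids <- c(promo_ids, p$promoter_id)
    }
  }
  nsites <- vapply(proms, function(p) nrow(p$sites), 1L)
  keys <- unlist(lapply(proms, function(p) p$sites$key), use.names = FALSE)
  key_levels <- sort_c(unique(keys %||% character()))
  structure(list(
    gene_ids = gene_ids,
    promoter_ids = promo_ids,
    promo_gene = as.integer(promo_gene),
    promo_off = as.integer(c(0L, cumsum(nsites))),
    site_start = as.integer(unlist(lapply(proms, function(p) p$sites$start),
                                   use.names = FALSE)),
    site_end = as.integer(unlist(lapply(proms, function(p) p$sites$end),
                                 use.names = FALSE)),
    site_key = match(keys, key_levels),
    key_levels = key_levels
  ), class = "packed_profiles")
}

#' @export
print.packed_profiles <- function(x, ...) {
  cat("<packed_profiles> ", length(x$gene_ids), " genes, ",
      length(x$promo_gene), " promoters, ", length(x$site_start),
      " sites, ", length(x$key_levels), " oriented keys\n", sep = "")
  invisible(x)
}

# Per-gene minimal spans (NA = absent) for an element sequence, over a
# packed profile set.
packed_min_spans <- function(packed, elements) {
  elements <- as_elements(elements)
  ids <- match(elements, packed$key_levels)
  n <- length(packed$gene_ids)
  if (anyNA(ids) || !length(packed$site_start)) {
    return(stats::setNames(rep(NA_real_, n), packed$gene_ids))
  }
  s <- cpp_min_spans(packed$site_start, packed$site_end,
                     as.integer(packed$site_key), packed$promo_off,
                     packed$promo_gene, n, as.integer(ids))
  stats::setNames(s, packed$gene_ids)
}

# Gene x oriented-key presence matrix from a packed profile set.
packed_key_presence <- function(packed) {
  n <- length(packed$gene_ids)
  k <- length(packed$key_levels)
  if (!k || !length(packed$site_start)) {
    m <- matrix(FALSE, n, k)
  } else {
    m <- cpp_key_gene_presence(as.integer(packed$site_key),
                               packed$promo_off, packed$promo_gene, n, k)
  }
  dimnames(m) <- list(packed$gene_ids, packed$key_levels)
  m
}
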