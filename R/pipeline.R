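# Full pipeline: batteries -> per-battery common-CRM search -> scoring
# -> significance filter -> TF inference, with a reproducibility
# manifest.

#' Read a battery table written by [write_batteries()]
#'
#' @param path TSV path.
#' @return list of battery objects.
#' @export
read_batteries <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(battery_id = df$battery_id[i], pattern = df$pattern[i],
                   pathway = df$pathway[i],
                   genes = strsplit(df$genes[i], ",", fixed = TRUE)[[1L]],
                   size = df$size[i], enrichment_p = df$enrichment_p[i]),
              class = "battery")
  })
  stats::setNames(out, df$battery_id)
}

# Resolve a pipeline input that may be a path or an in-memory object.
resolve_input <- function(x, reader, role) {
  if (is.null(x)) stop("missing pipeline input: ", role, call. = FALSE)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      stop("pipeline input '", role, "' not found at: ", x, call. = FALSE)
    }
    return(reader(x))
  }
  x
}

#' Run the complete CRM-discovery pipeline
#'
#' Builds gene batteries from expression patterns and pathway
#' enrichment, searches each battery for common CRMs, scores them
#' against the background, filters by the calibrated (or fixed)
#' significance threshold, decomposes the survivors into critical
#' transcription factors and writes all reports plus a run manifest.
#'
#' @param config named list (or path to a `key: value` DCF file whose
#'   values are file paths / scalars) with entries:
#'   \describe{
#'     \item{sites}{site table (path or data.frame) covering the
#'       battery genes.}
#'     \item{patterns}{pattern assignments (path or named list).}
#'     \item{pathways}{GMT pathways (path or named list).}
#'     \item{universe}{gene universe (path to one-id-per-line file or
#'       character vector).}
#'     \item{background}{background site table (path or data.frame).}
#'     \item{out_dir}{output directory (created).}
#'     \item{alpha_enrich}{battery enrichment level (default 0.05).}
#'     \item{delta, min_module_size, max_module_size}{search settings
#'       (defaults 0.7, 2, 3).}
#'     \item{thresholds}{optional calibration table (path or object).}
#'     \item{alpha}{fixed CRM significance level used when no
#'       calibration table is given (default 1e-4).}
#'     \item{min_batteries}{critical-TF frequency rule (default 3).}
#'     \item{seed}{recorded in the manifest (the pipeline itself is
#'       deterministic given its inputs).}
#'   }
#' @return (invisibly) list with batteries, crms (per battery),
#'   significant (per battery), tf_report, edges, manifest, status
#'   (0 = ok, 1 = no batteries / warnings).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    m <- read.dcf(config)
    config <- stats::setNames(as.list(m[1L, ]), colnames(m))
    for (k in c("alpha_enrich", "delta", "alpha")) {
      if (!is.null(config[[k]])) config[[k]] <- as.numeric(config[[k]])
    }
    for (k in c("min_module_size", "max_module_size", "min_batteries",
                "seed")) {
      if (!is.null(config[[k]])) config[[k]] <- as.integer(config[[k]])
    }
  }
  sites <- resolve_input(config$sites, read_site_table, "sites")
  patterns <- resolve_input(config$patterns, read_pattern_assignments,
                            "patterns")
  pathways <- resolve_input(config$pathways, read_gmt, "pathways")
  universe <- resolve_input(config$universe, readLines, "universe")
  background_tab <- resolve_input(config$background, read_site_table,
                                  "background")
  out_dir <- config$out_dir %||% stop("missing pipeline input: out_dir",
                                      call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- search_config(delta = config$delta %||% 0.7,
                       min_module_size = config$min_module_size %||% 2L,
                       max_module_size = config$max_module_size %||% 3L)
  alpha_enrich <- config$alpha_enrich %||% 0.05
  min_batteries <- config$min_batteries %||% 3L
  thresholds <- config$thresholds
  if (is.character(thresholds)) thresholds <- read_calibration(thresholds)
  alpha <- if (is.null(thresholds)) config$alpha %||% 1e-4 else NULL

  profiles <- build_gene_profiles(sites)
  background <- if (is.data.frame(background_tab)) {
    pack_profiles(build_gene_profiles(background_tab))
  } else {
    pack_profiles(background_tab) # gene profiles / packed passed directly
  }

  batteries <- build_batteries(patterns, pathways, universe,
                               alpha = alpha_enrich)
  status <- 0L
  if (!length(batteries)) {
    warning("no gene batteries pass enrichment; reports are empty",
            call. = FALSE)
    status <- 1L
  }
  all_crms <- list(); significant <- list()
  for (bat in batteries) {
    # genes without any annotated site are legitimate battery members:
    # they contribute an empty (site-free) promoter profile
    missing_genes <- setdiff(bat$genes, names(profiles))
    for (g in missing_genes) {
      profiles[[g]] <- gene_profile(g, list(
        build_promoter_profile(g, paste0(g, ".p1"), NULL)))
    }
    crms <- search_common_crms(profiles[bat$genes], cfg)
    crms <- score_crms(crms, background)
    all_crms[[bat$battery_id]] <- crms
    significant[[bat$battery_id]] <-
      select_significant(crms, bat$size, thresholds = thresholds,
                         alpha = alpha)
  }
  factor_sets <- lapply(significant, decompose_crms)
  tf_report <- if (length(factor_sets)) {
    critical_tfs(factor_sets, min_batteries = min_batteries)
  } else {
    data.frame(factor_id = character(), count = integer(),
               batteries = character(), stringsAsFactors = FALSE)
  }
  edges <- regulatory_edges(batteries, significant)

  write_batteries(batteries, file.path(out_dir, "batteries.tsv"))
  crm_tab <- combine_crm_tables(all_crms)
  data.table::fwrite(crm_tab, file.path(out_dir, "crms.tsv"), sep = "\t",
                     quote = FALSE, na = "NA")
  sig_tab <- combine_crm_tables(significant)
  data.table::fwrite(sig_tab, file.path(out_dir, "significant_crms.tsv"),
                     sep = "\t", quote = FALSE, na = "NA")
  write_tf_report(tf_report, file.path(out_dir, "tf_report.tsv"))
  write_edges(edges, file.path(out_dir, "edges.tsv"))
  manifest <- list(
    package = "crmbattery",
    version = as.character(packageVersion("crmbattery")),
    seed = config$seed %||% NA_integer_,
    parameters = list(alpha_enrich = alpha_enrich, delta = cfg$delta,
                      min_module_size = cfg$min_module_size,
                      max_module_size = cfg$max_module_size,
                      length_band = cfg$length_band,
                      alpha = alpha %||% NA_real_,
                      thresholds_used = !is.null(thresholds),
                      min_batteries = min_batteries),
    inputs = manifest_inputs(config),
    n_batteries = length(batteries),
    n_significant = sum(vapply(significant, length, 1L)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(batteries = batteries, crms = all_crms,
                 significant = significant, tf_report = tf_report,
                 edges = edges, manifest = manifest, status = status))
}

# Stack per-battery CRM sets into one table with a battery_id column.
combine_crm_tables <- function(crms_by_battery) {
  rows <- lapply(names(crms_by_battery), function(bid) {
    df <- as.data.frame.crm_set(crms_by_battery[[bid]])
    if (!nrow(df)) return(NULL)
    cbind(battery_id = bid, df, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(battery_id = character(), label = character(),
                      size = integer(), avg_len = numeric(),
                      min_len = numeric(), max_len = numeric(),
                      common_level = numeric(), support_genes = character(),
                      raw_support = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# md5 checksums for path-valued inputs; in-memory inputs are recorded
# by class.
manifest_inputs <- function(config) {
  keys <- c("sites", "patterns", "pathways", "universe", "background",
            "thresholds")
  out <- list()
  for (k in keys) {
    v <- config[[k]]
    if (is.null(v)) next
    out[[k]] <- if (is.character(v) && length(v) == 1L && file.exists(v)) {
      list(path = v, md5 = unname(tools::md5sum(v)))
    } else {
      list(class = class(v)[1L])
    }
  }
  out
}
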