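# Host-mobile-element linkage report: one deterministic per-element summary
# aggregating classification, spacer linkage, terminal repeats, coverage
# ratios and join evidence, emitted as agreeing JSON and TSV.

run_id_for <- function(contigs, config) {
  ids <- contig_ids(contigs)
  sprintf("run-%d-%d-%d-%d", config$seed, length(contigs),
          sum(vapply(contigs, `[[`, integer(1L), "length")),
          sum(utf8ToInt(paste(ids, collapse = ""))))
}

miuvig_block <- function(label) {
  list(
    source_of_uvig = "metagenome (synthetic or assembly)",
    virus_enrichment_approach = "not_computed",
    predicted_genome_type =
      if (label == "circular_mobile") "dsDNA" else
        if (label == "linear_tir_mobile") "dsDNA (linear)" else
          "not_computed",
    predicted_genome_structure =
      if (label == "circular_mobile") "circular" else
        if (label == "linear_tir_mobile") "linear" else "undetermined",
    detection_type = "independent sequence (UViG)",
    assembly_software = "not_computed",
    taxonomy = "not_computed",
    host_prediction_method = "not_computed"
  )
}

#' Build the host-element linkage report
#'
#' Aggregates the stage outputs into one per-element table plus a totals row,
#' available both machine-readable (JSON) and human-readable (TSV);
#' the two agree field for field. All inputs must come from the same run:
#' a mismatch between `run_id` attributes is an error.
#'
#' @param classifications Data frame from [classify()].
#' @param linkage Data frame from [summarize_linkage()].
#' @param repeats List of `terminal_repeat` objects.
#' @param ratios Named numeric vector of coverage ratios (contig id -> ratio),
#'   or `NULL`.
#' @param joins List of `join_proposal` objects, or `NULL`.
#' @param contigs The assembly (for lengths).
#' @param run_id Explicit run id; defaults to the common `run_id` attribute of
#'   the inputs, when set.
#' @return Object of class `"linkage_report"`: list with `run_id`, `host`,
#'   `table` (data frame) and `json` (list mirroring the table plus
#'   MIUViG-style blocks for viral elements).
#' @export
build_report <- function(classifications, linkage, repeats = list(),
                         ratios = NULL, joins = NULL, contigs, run_id = NULL) {
  rids <- unique(unlist(lapply(
    list(classifications, linkage, ratios, joins),
    function(x) attr(x, "run_id", exact = TRUE))))
  if (length(rids) > 1L) {
    stop("inputs carry different run ids: ", paste(rids, collapse = " vs "),
         call. = FALSE)
  }
  if (is.null(run_id)) run_id <- if (length(rids)) rids else "unversioned"

  ids <- classifications$contig_id
  lens <- vapply(ids, function(i) get_contig(contigs, i)$length, integer(1L))
  host <- classifications$contig_id[classifications$label == "chromosome"]
  host <- if (length(host)) host[1L] else NA_character_

  rep_kind <- rep(NA_character_, length(ids))
  rep_len <- rep(NA_integer_, length(ids))
  for (r in repeats) {
    i <- match(r$contig_id, ids)
    if (!is.na(i) && is.na(rep_kind[i])) {
      rep_kind[i] <- r$kind
      rep_len[i] <- r$length
    }
  }

  exact <- integer(length(ids))
  onemm <- integer(length(ids))
  if (nrow(linkage)) {
    m <- match(ids, linkage$target)
    exact <- ifelse(is.na(m), 0L, linkage$n_exact_spacers[m])
    onemm <- ifelse(is.na(m), 0L, linkage$n_one_mm_spacers[m])
  }

  ratio <- rep(NA_real_, length(ids))
  if (!is.null(ratios)) {
    m <- match(ids, names(ratios))
    ratio <- ifelse(is.na(m), NA_real_, unname(ratios)[m])
  }

  join_flag <- rep(FALSE, length(ids))
  circ_flag <- rep(FALSE, length(ids))
  if (!is.null(joins)) {
    for (j in joins) {
      for (cid in unique(c(j$contig_a, j$contig_b))) {
        i <- match(cid, ids)
        if (is.na(i)) next
        if (j$circularization) circ_flag[i] <- TRUE else join_flag[i] <- TRUE
      }
    }
  }

  tab <- data.frame(
    contig_id = ids, label = classifications$label, length = lens,
    n_exact_spacers = exact, n_one_mm_spacers = onemm,
    terminal_repeat_kind = rep_kind, terminal_repeat_length = rep_len,
    coverage_ratio = ratio, join_proposed = join_flag,
    circularization_proposed = circ_flag,
    evidence = classifications$evidence,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$label != "chromosome", tab$contig_id), , drop = FALSE]
  rownames(tab) <- NULL

  totals <- list(
    n_contigs = nrow(tab),
    n_mobile_elements = sum(!tab$label %in% c("chromosome", "unclassified")),
    n_exact_spacers = sum(tab$n_exact_spacers),
    n_one_mm_spacers = sum(tab$n_one_mm_spacers),
    n_joins_proposed = if (is.null(joins)) 0L else length(joins))

  elements <- lapply(seq_len(nrow(tab)), function(i) {
    el <- as.list(tab[i, , drop = FALSE])
    el <- lapply(el, function(v) if (is.factor(v)) as.character(v) else v)
    if (tab$label[i] %in% c("circular_mobile", "linear_tir_mobile")) {
      el$miuvig <- miuvig_block(tab$label[i])
    }
    el
  })

  structure(list(run_id = run_id, host = host, table = tab,
                 json = list(run_id = run_id, host = host,
                             elements = elements, totals = totals)),
            class = "linkage_report")
}

#' @export
print.linkage_report <- function(x, ...) {
  cat(sprintf("<linkage_report> %s  host=%s\n", x$run_id, x$host))
  cols <- c("contig_id", "label", "length", "n_exact_spacers",
            "n_one_mm_spacers", "coverage_ratio")
  print(x$table[, cols], row.names = FALSE)
  invisible(x)
}

#' Write a linkage report to disk
#'
#' Writes `report.json` and `report.tsv` (field-for-field the same content);
#' byte-identical across re-runs on identical inputs.
#'
#' @param report A `linkage_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  tsv_path <- file.path(dir, "report.tsv")
  jsonlite::write_json(report$json, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       na = "null")
  write.table(report$table, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(json_path, tsv_path))
}

#' Hit-position adjacency list for external plotting
#'
#' @param hits Hit table from [find_hits()].
#' @return Data frame `element`, `spacer_id`, `position`, `mismatches`.
#' @export
hit_adjacency <- function(hits) {
  data.frame(element = hits$target, spacer_id = hits$spacer_id,
             position = hits$start, mismatches = hits$mismatches,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline on an assembly
#'
#' Detects CRISPR arrays on every contig, matches all spacers against all
#' contigs (self-hits inside arrays excluded), detects terminal direct and
#' inverted repeats, computes coverage ratios, classifies contigs, profiles
#' nucleotide skews on the chromosome and calls a replication origin, proposes
#' array-evidence joins, and assembles the linkage report.
#'
#' @param contigs List of [contig()] objects.
#' @param depths Optional named depth vector (contig id -> mean depth). When
#'   `NULL`, per-contig `mean_depth` fields are used if all present.
#' @param config Configuration list from [default_config()].
#' @param chromosome_id Optional explicit chromosome designation (default:
#'   longest contig).
#' @return Object of class `"mobilome_run"`: list with `arrays`, `spacers`,
#'   `hits`, `linkage`, `repeats`, `ratios`, `classifications`, `skew`,
#'   `origin`, `joins`, `report`, `run_id`, `config`.
#' @export
run_pipeline <- function(contigs, depths = NULL, config = default_config(),
                         chromosome_id = NULL) {
  if (!length(contigs)) stop("empty assembly", call. = FALSE)
  rid <- run_id_for(contigs, config)
  log_run(config, "pipeline start: ", rid, " seed=", config$seed)

  if (is.null(depths)) {
    d <- vapply(contigs, function(x) {
      if (is.null(x$mean_depth)) NA_real_ else x$mean_depth
    }, numeric(1L))
    if (!anyNA(d)) {
      depths <- d
      names(depths) <- contig_ids(contigs)
    }
  }

  arrays <- unlist(lapply(contigs, detect_arrays, params = config),
                   recursive = FALSE)
  spacers <- collect_spacers(arrays)

  hits <- if (nrow(spacers)) {
    find_hits(spacers, contigs, max_mismatches = config$max_mismatches,
              exclude_arrays = config$exclude_arrays, target_arrays = arrays,
              params = config)
  } else {
    empty_hits()
  }
  linkage <- summarize_linkage(hits)

  ids <- contig_ids(contigs)
  lens <- vapply(contigs, `[[`, integer(1L), "length")
  if (is.null(chromosome_id)) chromosome_id <- ids[which.max(lens)]

  repeats <- list()
  for (cg in contigs) {
    if (cg$id == chromosome_id) next
    dr <- detect_circularity(cg, config$circ_min_overlap,
                             config$circ_max_mismatch)
    if (!is.null(dr)) repeats[[length(repeats) + 1L]] <- dr
    tr <- detect_tir(cg, config$tir_min_len, config$tir_min_identity,
                     config$tir_max_scan)
    if (!is.null(tr)) repeats[[length(repeats) + 1L]] <- tr
  }

  ratios <- NULL
  if (!is.null(depths) && chromosome_id %in% names(depths) &&
      depths[chromosome_id] > 0) {
    ratios <- vapply(ids, coverage_ratio, numeric(1L),
                     chromosome = chromosome_id, depths = depths)
    names(ratios) <- ids
  }

  classifications <- classify(contigs, arrays, hits, repeats, depths,
                              params = config, chromosome_id = chromosome_id)

  chrom <- get_contig(contigs, chromosome_id)
  skew <- if (chrom$length >= 3L * config$skew_window) {
    windowed_skews(chrom, config$skew_window, config$skew_step)
  } else {
    NULL
  }
  origin <- if (!is.null(skew) && length(skew$start) >= 3L) {
    find_origin(skew)
  } else {
    NULL
  }

  joins <- propose_joins(contigs, arrays, min_k = config$min_k,
                         params = config)

  attr(classifications, "run_id") <- rid
  attr(linkage, "run_id") <- rid
  if (!is.null(ratios)) attr(ratios, "run_id") <- rid
  if (!is.null(joins)) attr(joins, "run_id") <- rid

  report <- build_report(classifications, linkage, repeats, ratios, joins,
                         contigs, run_id = rid)

  structure(list(
    run_id = rid, config = config, chromosome_id = chromosome_id,
    arrays = arrays, spacers = spacers, hits = hits, linkage = linkage,
    repeats = repeats, ratios = ratios, classifications = classifications,
    skew = skew, origin = origin, joins = joins, report = report
  ), class = "mobilome_run")
}

#' @export
print.mobilome_run <- function(x, ...) {
  cat(sprintf("<mobilome_run> %s\n", x$run_id))
  cat(sprintf("  %d contig(s), %d array(s), %d spacer(s), %d hit(s), %d join proposal(s)\n",
              nrow(x$classifications), length(x$arrays), nrow(x$spacers),
              nrow(x$hits), length(x$joins)))
  if (!is.null(x$origin)) {
    cat(sprintf("  origin call on %s: position %d\n", x$chromosome_id,
                x$origin$position))
  }
  print(x$report)
  invisible(x)
}

#' @export
summary.mobilome_run <- function(object, ...) {
  print(object)
  invisible(object$report$table)
}
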