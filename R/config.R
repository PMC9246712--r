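#' Default run configuration
#'
#' One flat list of every tunable threshold in the pipeline, each with a
#' defined default. A serialised config round-trips losslessly through
#' [write_config()] / [read_config()]. One global `seed` governs every
#' stochastic operation.
#'
#' Generator (`sim_*`) parameters define the planted study conditions:
#' a 60 kb strand-biased chromosome carrying two CRISPR arrays (20 + 10
#' spacers, 30 nt repeats, spacers 35-42 nt) flanking a marker locus; two
#' plain mobile contigs; one circular virus represented with a 30 nt
#' duplicated terminus; one linear virus with 80 nt terminal inverted repeats
#' and 3.5x chromosome depth carrying 3 exact plus 3 one-mismatch
#' protospacers; 9 exact-match spacers in total across the 4 mobile contigs.
#'
#' @return A named list of class `"spacerlink_config"`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,

    # --- synthetic assembly -------------------------------------------------
    sim_chromosome_length = 60000L,
    sim_gc_content        = 0.41,
    sim_skew_bias         = 0.04,   # per-base G-vs-C excess on each replichore
    sim_at_bias           = 0.06,   # corroborating A-vs-T excess; kept above
                                    # the GC bias so the amino-keto (MK) track
                                    # also dips at the origin
    sim_repeat_length     = 30L,
    sim_array1_spacers    = 20L,
    sim_array2_spacers    = 10L,
    sim_spacer_min        = 35L,    # planted spacer length range (nt)
    sim_spacer_max        = 42L,
    sim_marker_length     = 2000L,
    sim_n_plain_mobile    = 2L,
    sim_plain_mobile_length   = 8000L,
    sim_circular_virus_length = 10000L,
    sim_circular_overlap      = 30L,   # duplicated terminus of the circular virus
    sim_linear_virus_length   = 12000L,
    sim_tir_length            = 80L,
    sim_tir_mismatches        = 0L,
    sim_exact_per_plain       = 2L,    # exact protospacers per plain mobile contig
    sim_exact_circular        = 2L,
    sim_exact_linear          = 3L,
    sim_onemm_linear          = 3L,
    sim_chromosome_depth      = 20,
    sim_virus_depth_multiplier      = 3.5,
    sim_circular_depth_multiplier   = 2.0,
    sim_plain_depth_multiplier      = 1.0,
    sim_decoy_in_array        = FALSE,  # adversarial mode: duplicate one spacer
                                        # between the two arrays to exercise the
                                        # self-hit filter

    # --- CRISPR array detection --------------------------------------------
    min_repeats        = 3L,
    seed_k             = 13L,
    repeat_min         = 23L,
    repeat_max         = 50L,
    spacer_min         = 20L,
    spacer_max         = 50L,
    gap_spread         = 12L,
    min_col_agreement  = 0.8,
    repeat_edge_agreement = 0.95,  # near-unanimity required at repeat edges
    edge_window        = 500L,

    # --- spacer matching ----------------------------------------------------
    max_mismatches = 1L,
    exclude_arrays = TRUE,
    min_spacer_query = 15L,

    # --- element classification --------------------------------------------
    circ_min_overlap   = 20L,
    circ_max_mismatch  = 0L,
    tir_min_len        = 20L,
    tir_min_identity   = 0.85,
    tir_max_scan       = 500L,
    coverage_ratio_threshold = 2.0,
    array_fraction_threshold = 0.5,

    # --- skew / origin ------------------------------------------------------
    skew_window = 1000L,
    skew_step   = 1000L,

    # --- array joins --------------------------------------------------------
    min_k            = 4L,
    repeat_tol       = 0.1,   # tolerated mismatch fraction in overlap repeats
    partial_spacer_frac = 0.9,

    verbose = FALSE
  ), class = "spacerlink_config")
}

#' Build a configuration with overrides
#'
#' @param ... Named overrides of [default_config()] entries.
#' @return A `"spacerlink_config"` list.
#' @export
spacerlink_config <- function(...) {
  cfg <- default_config()
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown config parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(dots)) {
      val <- dots[[nm]]
      tmpl <- cfg[[nm]]
      if (is.integer(tmpl)) val <- as.integer(val)
      if (is.double(tmpl)) val <- as.numeric(val)
      if (is.logical(tmpl)) val <- as.logical(val)
      cfg[[nm]] <- val
    }
  }
  cfg
}

#' Write a configuration to a YAML file
#' @param config A `"spacerlink_config"` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to their defaults, so a
#' partial file is a valid override set.
#'
#' @param path YAML file written by [write_config()] (or hand-written flat
#'   key-value mapping).
#' @return A `"spacerlink_config"` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(spacerlink_config, vals)
}

# Echo seed and config at pipeline start; plain-text reproducibility log.
log_run <- function(config, ...) {
  if (isTRUE(config$verbose)) {
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  }
  invisible(NULL)
}
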