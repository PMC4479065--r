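# End-to-end orchestration: per-population QC, LD, phase consistency,
# ancestral Ne and G-matrix PCA, with every report written as CSV and a
# manifest recording all thresholds and the seed.  Populations are QC'd
# independently; cross-population stages (phase, PCA) use the
# intersection of the per-population QC survivor marker sets.

#' Pipeline configuration
#'
#' @param qc Either a single [qc_config()] applied to every population or
#'   a named list of them keyed by population label (the usual use: a
#'   lower MAF threshold for the large populations, a higher one for the
#'   small).
#' @param bins [bin_scheme()] for decay and phase tables.
#' @param max_dist_mb Maximum LD pair distance (Mb).
#' @param ne_time_points Time grid for the Ne trajectory.
#' @param cm_per_mb Genetic-to-physical scale.
#' @param phase_window_upper,phase_window_lower Distance windows (Mb) for
#'   the two pooled aggregates of the phase matrix.
#' @param pca_k Number of principal components.
#' @param out_dir Output directory for report CSVs (`NULL`: no files).
#' @param seed Integer seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed also feeds any upstream simulation).
#' @return An object of class `run_config`.
#' @export
run_config <- function(qc = qc_config(),
                       bins = default_bins(),
                       max_dist_mb = 15,
                       ne_time_points = ne_time_grid(),
                       cm_per_mb = 1,
                       phase_window_upper = c(0, 0.2),
                       phase_window_lower = c(0.02, 0.03),
                       pca_k = 10L,
                       out_dir = NULL,
                       seed = 1L) {
  structure(list(qc = qc, bins = bins, max_dist_mb = max_dist_mb,
                 ne_time_points = ne_time_points, cm_per_mb = cm_per_mb,
                 phase_window_upper = phase_window_upper,
                 phase_window_lower = phase_window_lower,
                 pca_k = as.integer(pca_k), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

qc_for_pop <- function(cfg, pop) {
  if (inherits(cfg$qc, "qc_config")) return(cfg$qc)
  if (pop %in% names(cfg$qc)) return(cfg$qc[[pop]])
  stop("no QC configuration for population '", pop, "'")
}

#' Run the full multi-population pipeline
#'
#' Sequences QC, adjacent LD, LD decay, phase consistency, ancestral Ne
#' and G-matrix PCA over a set of populations, and (when `out_dir` is
#' set) writes each report as CSV plus a manifest of every parameter.
#' Stages fail with a stage-named error rather than emitting partial
#' tables.
#'
#' @param populations Named list of [genotypes] objects (one population
#'   each) or a named character vector of PLINK path prefixes.
#' @param config A [run_config()].
#' @return List of class `ld_run`: `qc_table`, `qc` (per-population QC
#'   results), `map_summary`, `adjacent`, `decay`, `ld` (per-population
#'   pair tables), `phase_matrix`, `phase_bins`, `ne`, `pca`, `manifest`.
#' @export
run_all <- function(populations, config = run_config()) {
  stopifnot(inherits(config, "run_config"), length(populations) >= 1,
            !is.null(names(populations)))
  if (is.character(populations))
    populations <- lapply(populations, read_plink)
  pops <- names(populations)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  qc_res <- stage("qc", lapply(pops, function(p)
    apply_qc(populations[[p]], qc_for_pop(config, p))))
  names(qc_res) <- pops
  qc_table <- qc_report_table(lapply(qc_res, `[[`, "report"))

  filtered <- lapply(qc_res, `[[`, "genotypes")
  map_summary <- stage("map_summary",
                       summarize_map(filtered[[1]]$map))

  ld_tables <- stage("ld", lapply(filtered, ld_pairs,
                                  max_dist_mb = config$max_dist_mb))
  adjacent <- stage("adjacent_ld", {
    tabs <- lapply(pops, function(p) {
      a <- adjacent_ld(filtered[[p]])
      cbind(pop = p, a, stringsAsFactors = FALSE)
    })
    do.call(rbind, tabs)
  })
  decay <- stage("ld_decay", {
    tabs <- lapply(pops, function(p)
      cbind(pop = p, as.data.frame(ld_decay(ld_tables[[p]],
                                            bins = config$bins,
                                            max_dist_mb = config$max_dist_mb)),
            stringsAsFactors = FALSE))
    do.call(rbind, tabs)
  })

  phase_mat <- NULL; phase_bins <- NULL
  if (length(pops) >= 2) {
    phase_mat <- stage("phase", phase_matrix(
      ld_tables, config$phase_window_upper, config$phase_window_lower))
    phase_bins <- stage("phase", {
      rows <- list()
      for (a in seq_along(pops)) for (b in seq_along(pops)) {
        if (a >= b) next
        sh <- shared_pairs(ld_tables[[a]], ld_tables[[b]])
        pc <- phase_consistency(sh, config$bins)
        rows[[length(rows) + 1L]] <-
          cbind(pop_a = pops[a], pop_b = pops[b], as.data.frame(pc),
                stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
  }

  ne_tabs <- stage("ne", {
    tabs <- lapply(pops, function(p) {
      tr <- as.data.frame(suppressWarnings(
        ne_trajectory(ld_tables[[p]],
                      time_points = config$ne_time_points,
                      cm_per_mb = config$cm_per_mb)))
      if (nrow(tr) == 0L) return(NULL)
      cbind(pop = p, tr, stringsAsFactors = FALSE)
    })
    do.call(rbind, tabs)
  })

  pca_res <- stage("pca", {
    common <- Reduce(intersect, lapply(filtered, function(g) g$map$name))
    if (length(common) < 2)
      stop("fewer than 2 markers pass QC in every population")
    merged <- merge_populations(lapply(filtered, subset_genotypes,
                                       markers = common))
    pca_g(build_G(merged), k = min(config$pca_k, nrow(merged$doses)))
  })

  manifest <- c(
    package_version = as.character(packageVersion("ldphase")),
    seed = config$seed,
    populations = paste(pops, collapse = ","),
    max_dist_mb = config$max_dist_mb,
    cm_per_mb = config$cm_per_mb,
    n_bins = config$bins$n_bins,
    bin_edges = paste(config$bins$edges, collapse = ","),
    ne_time_points = paste(config$ne_time_points, collapse = ","),
    pca_k = config$pca_k,
    unlist(lapply(pops, function(p) {
      q <- qc_for_pop(config, p)
      setNames(as.character(c(q$maf_min, q$snp_call_rate_min, q$hwe_p_min,
                              q$het_excess_max, q$ind_call_rate_min)),
               paste0("qc_", p, "_",
                      c("maf_min", "snp_call_rate_min", "hwe_p_min",
                        "het_excess_max", "ind_call_rate_min")))
    })))

  out <- structure(list(qc_table = qc_table, qc = qc_res,
                        map_summary = map_summary, adjacent = adjacent,
                        decay = decay, ld = ld_tables,
                        phase_matrix = phase_mat, phase_bins = phase_bins,
                        ne = ne_tabs, pca = pca_res, manifest = manifest),
                   class = "ld_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) write.csv(df, file.path(config$out_dir, f),
                                    row.names = FALSE)
    wr(qc_table, "qc_report.csv")
    wr(map_summary, "map_summary.csv")
    wr(adjacent, "adjacent_ld.csv")
    wr(decay, "ld_decay.csv")
    if (!is.null(phase_mat))
      write.csv(phase_mat, file.path(config$out_dir, "phase_matrix.csv"))
    if (!is.null(phase_bins)) wr(phase_bins, "phase_bins.csv")
    wr(ne_tabs, "ne_trajectory.csv")
    scores <- data.frame(id = pca_res$ids, pop = pca_res$pop,
                         pca_res$scores, check.names = FALSE)
    wr(scores, "pca_scores.csv")
    writeLines(paste(names(manifest), manifest, sep = "="),
               file.path(config$out_dir, "manifest.txt"))
  }
  out
}

#' Stack several single-population genotype sets on a shared marker set
#'
#' All inputs must have identical marker maps and dose orientation
#' (subset them to a common marker list first).
#'
#' @param gs List of [genotypes] objects.
#' @return One [genotypes] object containing all individuals.
#' @export
merge_populations <- function(gs) {
  stopifnot(length(gs) >= 1)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!identical(g$map$name, ref$map$name) ||
        !identical(g$ref_allele, ref$ref_allele))
      stop("populations must share an identical marker map and dose ",
           "orientation before merging")
  }
  genotypes(do.call(rbind, lapply(gs, `[[`, "doses")),
            ref$map,
            do.call(rbind, lapply(gs, `[[`, "samples")),
            ref$ref_allele, ref$alt_allele)
}
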