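# Config-driven orchestration: trajectory -> filtered, classified
# stabilization-center tables, dihedrals, psi association, conservation.

#' Pipeline run configuration
#'
#' @param trajectory A trajectory object, or a path to a multi-model PDB.
#' @param topology A [topology_config()].
#' @param alignment Optional path to an aligned FASTA (or an
#'   `msa_alignment`) for the conservation table.
#' @param cparams,sparams,window Analysis parameters; see
#'   [contact_params()], [sc_params()], [psi_window()].
#' @param tracked_res_seq Residue numbers whose psi series are tabulated in
#'   every chain (default 59, 191, 193 — the extracellular-loop prolines).
#' @param assoc_res_seq Residue number whose psi drives the association
#'   statistic for each trans-interface pair (default 193).
#' @param n_perm Permutations for the association test (default 1000).
#' @param seed Integer seed recorded in every output.
#' @param out_dir Output directory (created; writes are atomic: outputs are
#'   staged and moved into place, nothing partial is left on failure).
#' @return An object of class `run_config`.
#' @export
run_config <- function(trajectory, topology, alignment = NULL,
                       cparams = contact_params(), sparams = sc_params(),
                       window = psi_window(), tracked_res_seq = c(59, 191, 193),
                       assoc_res_seq = 193, n_perm = 1000, seed = 1,
                       out_dir = "sctraj_out") {
  if (is.character(trajectory) && !file.exists(trajectory))
    stop_sctraj("sctraj_config", "trajectory file not found: %s", trajectory)
  if (is.character(alignment) && !file.exists(alignment))
    stop_sctraj("sctraj_config", "alignment file not found: %s", alignment)
  structure(list(trajectory = trajectory, topology = topology,
                 alignment = alignment, cparams = cparams,
                 sparams = sparams, window = window,
                 tracked_res_seq = tracked_res_seq,
                 assoc_res_seq = assoc_res_seq,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_sctraj("sctraj_stage", "stage '%s' failed: %s", name,
                conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Stages: read the trajectory, build stabilization-center time series,
#' apply the extracellular and occurrence filters, classify pairs by
#' topology, tabulate tracked psi series, compute the psi association for
#' each retained trans-interface pair (psi of `assoc_res_seq` in the pair's
#' two chains, any-aggregated), and, when an alignment is supplied, the
#' conservation table.  Outputs are TSV files plus a manifest; identical
#' config and seed give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the output paths and the in-memory
#'   results (`series`, `dihedrals`, `associations`, `conservation`).
#' @export
run_pipeline <- function(config) {
  traj <- run_stage("read", {
    if (is.character(config$trajectory)) read_pdb(config$trajectory)
    else config$trajectory
  })
  topo <- config$topology
  vdw <- default_vdw_table()

  series <- run_stage("sc_dynamics", {
    s <- sc_time_series(traj, vdw, config$cparams, config$sparams)
    s <- filter_extracellular(s, topo)
    s <- filter_occurrence(s, topo)
    classify_series(s, topo)
  })

  dihedrals <- run_stage("dihedrals", {
    chains <- sort(unique(traj$atoms$chain))
    rows <- list()
    for (ch in chains) for (rs in config$tracked_res_seq) {
      ds <- tryCatch(residue_dihedral_series(traj, ch, rs, "psi"),
                     sctraj_not_computable = function(e) NULL)
      if (!is.null(ds))
        rows[[length(rows) + 1]] <- data.frame(
          chain = ch, res_seq = rs, frame = seq_along(ds$values_deg),
          psi_deg = ds$values_deg, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else data.frame()
  })

  associations <- run_stage("association", {
    out <- list()
    if (nrow(series$pairs) > 0) {
      trans <- which(series$pairs$class == "TRANS_GJ")
      for (k in trans) {
        p <- series$pairs[k, ]
        psi_list <- list()
        for (ch in unique(c(p$chain_u, p$chain_v))) {
          ds <- tryCatch(
            residue_dihedral_series(traj, ch, config$assoc_res_seq, "psi"),
            sctraj_not_computable = function(e) NULL)
          if (!is.null(ds)) psi_list[[length(psi_list) + 1]] <- ds
        }
        if (length(psi_list) == 0) next
        assoc <- correlate_sc_dihedral(series$presence[, k], psi_list,
                                       config$window, config$n_perm,
                                       seed = config$seed)
        out[[length(out) + 1]] <- data.frame(
          pair = pair_key(p$uid_u, p$uid_v),
          res_seq_psi = config$assoc_res_seq,
          window_lo = config$window$lo_deg, window_hi = config$window$hi_deg,
          occ_in_window = assoc$occ_in_window,
          occ_out_window = assoc$occ_out_window,
          odds_ratio = assoc$odds_ratio, perm_p = assoc$perm_p,
          n_perm = assoc$n_perm, seed = assoc$seed,
          flagged = assoc$flagged, stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else data.frame()
  })

  conservation <- NULL
  if (!is.null(config$alignment)) {
    conservation <- run_stage("conservation", {
      aln <- if (is.character(config$alignment))
        read_fasta_alignment(config$alignment) else config$alignment
      column_stats(aln)
    })
  }

  # stage everything, then move into place atomically
  out_dir <- config$out_dir
  stage_dir <- paste0(out_dir, ".staging")
  unlink(stage_dir, recursive = TRUE)
  dir.create(stage_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage_dir, recursive = TRUE))

  sc_table <- series$pairs
  if (nrow(series$pairs) > 0) {
    sc_table <- series$pairs[, c("chain_u", "res_seq_u", "res_name_u",
                                 "chain_v", "res_seq_v", "res_name_v",
                                 "class", "occupancy", "first_frame",
                                 "last_frame", "mean_min_dist_A")]
  }
  write_tsv(sc_table, file.path(stage_dir, "sc_table.tsv"))
  pm <- as.data.frame(series$presence * 1L)
  pm <- cbind(frame = seq_len(nrow(series$presence)), pm)
  write_tsv(pm, file.path(stage_dir, "presence_matrix.tsv"))
  write_tsv(dihedrals, file.path(stage_dir, "dihedrals.tsv"))
  write_tsv(associations, file.path(stage_dir, "associations.tsv"))
  if (!is.null(conservation))
    write_tsv(conservation, file.path(stage_dir, "conservation.tsv"))

  manifest <- c(
    sprintf("sctraj_version: %s",
            as.character(utils::packageVersion("sctraj"))),
    sprintf("seed: %d", config$seed),
    sprintf("n_frames: %d", n_frames(traj)),
    sprintf("frame_interval_ps: %g", traj$frame_interval_ps),
    sprintf("margin_A: %g", config$cparams$margin_A),
    sprintf("min_seq_separation: %d", config$cparams$min_seq_separation),
    sprintf("use_heavy_only: %s", config$cparams$use_heavy_only),
    sprintf("support_threshold: %d", config$sparams$support_threshold),
    sprintf("truncation_rule: %s", config$sparams$truncation_rule),
    sprintf("min_occurrence_frac: %g", config$topology$min_occurrence_frac),
    sprintf("extracellular_ranges: %s",
            paste(vapply(config$topology$extracellular_ranges,
                         function(r) sprintf("%d-%d", r[1], r[2]),
                         character(1)), collapse = ", ")),
    sprintf("psi_window: [%g, %g]", config$window$lo_deg,
            config$window$hi_deg),
    sprintf("tracked_res_seq: %s",
            paste(config$tracked_res_seq, collapse = ", ")),
    sprintf("n_perm: %d", config$n_perm)
  )
  writeLines(manifest, file.path(stage_dir, "run_manifest.txt"))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage_dir))
    file.rename(file.path(stage_dir, f), file.path(out_dir, f))
  unlink(stage_dir, recursive = TRUE)
  ok <- TRUE

  invisible(list(out_dir = out_dir, series = series, dihedrals = dihedrals,
                 associations = associations, conservation = conservation))
}
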