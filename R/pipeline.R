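#' Run the full heterogeneity analysis
#'
#' Orchestrates the stages in order: (optional) alignment and overhang
#' trimming, variable-site profiling, substitution spectra per group,
#' variable-region detection plus the canonical fixed windows, ambiguity
#' reconciliation of consensus records, structural-effect classification and
#' compensatory typing against the hairpin model, distance/NJ/bootstrap
#' phylogenetics, and the Phi recombination test. Returns a single report
#' list and (optionally) writes every artifact under `out_dir`.
#'
#' @param aln An [rd_alignment()] of the clone sequences (pre-aligned), or a
#'   named character vector of unaligned sequences (then aligned with
#'   [align_center_star()]).
#' @param grouping Named character vector id -> group.
#' @param consensus Optional named character vector of consensus sequences
#'   aligned to the same coordinates (ids e.g. accession numbers).
#' @param pair_table Optional `rd_pair_table` hairpin model in reference
#'   coordinates (default: the bundled fixture model when the alignment
#'   spans it).
#' @param vr_windows Data frame `label`/`start`/`end` of canonical variable
#'   regions (default [fixture_vr_windows()]).
#' @param model Distance model for the tree stage.
#' @param bootstrap_replicates Bootstrap replicates (0 disables supports).
#' @param phi_window,phi_permutations Phi test parameters.
#' @param seed Seed for all stochastic stages (mandatory when any runs).
#' @param outgroup Optional consensus/clone id to root the tree on.
#' @param out_dir Optional output directory.
#' @return List of class `rd_report`.
#' @export
run_all <- function(aln, grouping, consensus = NULL, pair_table = NULL,
                    vr_windows = fixture_vr_windows(), model = "F84",
                    bootstrap_replicates = 100L, phi_window = 100L,
                    phi_permutations = 1000L, seed = NULL, outgroup = NULL,
                    out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(seed) && (bootstrap_replicates > 0 || phi_permutations > 0))
    stop("seed is mandatory when stochastic stages are enabled")
  if (!inherits(aln, "rd_alignment"))
    aln <- stage("align", align_center_star(aln))
  clone_ids <- intersect(names(aln$seqs), names(grouping))
  if (length(clone_ids) == 0) stop("no records match the grouping")

  sites <- stage("profile", profile_variable_sites(
    rd_alignment(aln$seqs[clone_ids], aln$offset), grouping))
  groups <- attr(sites, "groups")
  spectra <- stage("spectrum",
    lapply(stats::setNames(groups, groups), function(g)
      substitution_spectrum(sites, g)))
  regions_detected <- stage("regions", detect_variable_regions(sites))
  region_counts <- stats::setNames(
    vapply(seq_len(nrow(vr_windows)), function(i)
      length(sites_in_window(sites, vr_windows$start[i],
                             vr_windows$end[i])), integer(1)),
    vr_windows$label)

  clone_aln <- rd_alignment(aln$seqs[clone_ids], aln$offset)
  ambiguity <- NULL
  if (!is.null(consensus)) {
    ambiguity <- stage("ambiguity", {
      rows <- lapply(names(consensus), function(id) {
        grp <- attr(consensus, "groups")[id]
        pool <- if (!is.null(grp) && !is.na(grp))
          clone_ids[grouping[clone_ids] == grp] else clone_ids
        chk <- check_ambiguity_consistency(consensus[id],
          profile_variable_sites(
            rd_alignment(clone_aln$seqs[pool], clone_aln$offset),
            grouping[pool]),
          clone_aln, clone_ids = pool)
        if (nrow(chk) > 0) cbind(consensus_id = id, chk) else NULL
      })
      do.call(rbind, rows)
    })
  }

  if (is.null(pair_table) &&
      aln$offset == 1 && n_columns(aln) >= 452) {
    pair_table <- fixture_pair_table()
  }
  structure_tab <- NULL
  comp_types <- NULL
  integrity <- NULL
  if (!is.null(pair_table)) {
    structure_tab <- stage("structure",
      structural_effects(pair_table, sites, clone_aln))
    comp_types <- stage("compensatory", {
      cons_ids <- if (!is.null(consensus)) names(consensus) else character(0)
      full <- if (!is.null(consensus))
        rd_alignment(c(clone_aln$seqs, consensus), clone_aln$offset)
        else clone_aln
      compensatory_type_table(full, consensus_ids = cons_ids)
    })
    integrity <- stage("integrity", clone_pairing_integrity(clone_aln))
  }

  tree_res <- stage("tree", {
    if (bootstrap_replicates > 0) {
      bootstrap_support(clone_aln, model = model,
                        replicates = bootstrap_replicates, seed = seed)
    } else {
      list(tree = neighbor_joining(distance_matrix(clone_aln, model)),
           n_replicates = 0L, n_effective = 0L)
    }
  })
  tree <- tree_res$tree
  if (!is.null(outgroup) && outgroup %in% tree$tip.label)
    tree <- stage("root", outgroup_root(tree, outgroup))
  dm <- stage("distances", distance_matrix(clone_aln, model))
  pw <- stage("pairwise", pairwise_differences(clone_aln))

  phi <- stage("phi", phi_permutation_test(clone_aln, w = phi_window,
                                           n_permutations = phi_permutations,
                                           seed = seed))

  report <- structure(list(
    n_records = length(clone_ids),
    n_columns = n_columns(clone_aln),
    offset = clone_aln$offset,
    groups = groups,
    n_variable_sites = nrow(sites),
    sites = sites,
    spectra = spectra,
    regions_detected = regions_detected,
    region_counts = region_counts,
    ambiguity = ambiguity,
    structure = structure_tab,
    compensatory_types = comp_types,
    pairing_integrity = integrity,
    pairwise = pw,
    distance_model = model,
    tree = tree,
    bootstrap = tree_res[c("n_replicates", "n_effective")],
    phi = phi,
    seed = seed
  ), class = "rd_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.rd_report <- function(x, ...) {
  cat(sprintf("rd_report: %d records, %d variable sites (%s)\n",
              x$n_records, x$n_variable_sites,
              paste(sprintf("%s=%d", names(x$region_counts),
                            x$region_counts), collapse = ", ")))
  for (g in x$groups) {
    s <- x$spectra[[g]]
    cat(sprintf("  %s: %d variable sites, ts %s%%, T-C among ts %s%%\n",
                g, s$n_variable_sites, s$pct_transitions,
                s$pct_TC_among_transitions))
  }
  cat(sprintf("  Phi = %.4f, p = %.4g\n", x$phi$statistic, x$phi$p_value))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write every report artifact to a directory
#'
#' Emits `variable_sites.tsv`, `spectrum.json`, `regions.tsv`,
#' `ambiguity_checks.tsv`, `pairwise.tsv`, `structure_effects.tsv`,
#' `compensatory_types.tsv`, `tree.nwk`, `distances.tsv` and `phi.json`
#' plus a consolidated `report.json`.
#'
#' @param report An `rd_report`.
#' @param out_dir Directory (created if absent).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(report$sites, p("variable_sites.tsv"))
  jsonlite::write_json(lapply(report$spectra, unclass), p("spectrum.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tsv(report$regions_detected, p("regions.tsv"))
  if (!is.null(report$ambiguity))
    write_tsv(report$ambiguity, p("ambiguity_checks.tsv"))
  pwdf <- as.data.frame(report$pairwise$subst)
  pwdf <- cbind(id = rownames(report$pairwise$subst), pwdf)
  write_tsv(pwdf, p("pairwise.tsv"))
  if (!is.null(report$structure))
    write_tsv(report$structure, p("structure_effects.tsv"))
  if (!is.null(report$compensatory_types))
    write_tsv(report$compensatory_types, p("compensatory_types.tsv"))
  ape::write.tree(report$tree, p("tree.nwk"))
  jsonlite::write_json(unclass(report$phi), p("phi.json"),
                       auto_unbox = TRUE, digits = NA)
  summary <- list(
    n_records = report$n_records,
    n_variable_sites = report$n_variable_sites,
    region_counts = as.list(report$region_counts),
    spectra = lapply(report$spectra, unclass),
    ambiguity_consistent = if (!is.null(report$ambiguity))
      sum(report$ambiguity$verdict == "consistent") else NULL,
    ambiguity_checked = if (!is.null(report$ambiguity))
      sum(report$ambiguity$verdict != "uninformative") else NULL,
    max_subst = report$pairwise$max_subst,
    max_pct = report$pairwise$max_pct,
    identical_pairs = report$pairwise$identical_pairs,
    distance_model = report$distance_model,
    bootstrap = report$bootstrap,
    phi = unclass(report$phi),
    seed = report$seed
  )
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}
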