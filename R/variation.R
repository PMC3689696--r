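#' Classify the substitution type of a site's state set
#'
#' Gaps are removed first; the residual base set decides the class:
#' one base -> `not_variable` (or `indel` if a gap was present and the column
#' varies only by the gap), `{A,G}` or `{C,T}` -> `transition`, any other
#' two-base set -> `transversion`, three or more bases -> `multistate`.
#' The presence of a gap is reported as an orthogonal flag, so a site such as
#' A/T/- is a transversion site that additionally involves an indel.
#'
#' @param states Character vector of observed states (may include `-`; T/U
#'   equivalent).
#' @return List with `class` (character) and `indel` (logical).
#' @export
classify_substitution <- function(states) {
  states <- toupper(states)
  states <- ifelse(states == "U", "T", states)
  states <- unique(states)
  has_gap <- "-" %in% states
  bases <- setdiff(states, "-")
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("states must be unambiguous bases or '-': ",
         paste(states, collapse = ","))
  cls <-
    if (length(bases) <= 1) {
      if (has_gap && length(bases) == 1) "indel" else "not_variable"
    } else if (length(bases) == 2) {
      if (setequal(bases, c("A", "G")) || setequal(bases, c("C", "T")))
        "transition" else "transversion"
    } else "multistate"
  list(class = cls, indel = has_gap)
}

site_states <- function(column_chars) sort(unique(column_chars))

#' Profile variable sites of an alignment
#'
#' One row per non-invariant column (columns where any two records differ,
#' including by a gap). States are recorded per group and pooled; the pooled
#' `site_class` follows the convention: `dimorphic` = exactly two non-gap
#' states and no gap, `multistate` = three or more non-gap states,
#' `indel_involved` = a gap plus at most two non-gap states; the `indel`
#' column flags gap involvement orthogonally. Per-group substitution classes
#' come from [classify_substitution()].
#'
#' @param aln An [rd_alignment()].
#' @param grouping Named character vector mapping record id -> group label.
#' @return Data frame of class `rd_variable_sites` with columns `position`,
#'   `site_class`, `indel`, `pooled_states`, and per group `states_<group>`
#'   and `class_<group>` (states as `/`-joined strings, e.g. `"A/G"`).
#' @export
profile_variable_sites <- function(aln, grouping) {
  m <- aln_matrix(aln)
  if (nrow(m) < 1 || ncol(m) < 1) stop("empty alignment")
  ids <- rownames(m)
  if (!all(ids %in% names(grouping)))
    stop("records missing from grouping: ",
         paste(setdiff(ids, names(grouping)), collapse = ", "))
  groups <- unique(unname(grouping[ids]))
  variable <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  rows <- lapply(variable, function(j) {
    col <- m[, j]
    pooled <- site_states(col)
    bases <- setdiff(pooled, "-")
    has_gap <- "-" %in% pooled
    site_class <-
      if (length(bases) >= 3) "multistate"
      else if (!has_gap && length(bases) == 2) "dimorphic"
      else if (has_gap) "indel_involved"
      else "invariant"   # unreachable: column was variable
    row <- list(position = column_position(aln, j),
                site_class = site_class,
                indel = has_gap,
                pooled_states = paste(pooled, collapse = "/"))
    for (g in groups) {
      st <- site_states(col[grouping[ids] == g])
      cl <- classify_substitution(st)
      row[[paste0("states_", g)]] <- paste(st, collapse = "/")
      row[[paste0("class_", g)]] <- cl$class
    }
    row
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                stringsAsFactors = FALSE)))
  if (is.null(out))
    out <- data.frame(position = integer(0), site_class = character(0),
                      indel = logical(0), pooled_states = character(0))
  class(out) <- c("rd_variable_sites", "data.frame")
  attr(out, "groups") <- groups
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Substitution spectrum of one group
#'
#' Counts are per SITE over the group's variable sites: a site enters the
#' transition/transversion denominator when its gap-removed state set has
#' exactly two bases (a gap at the site does not exclude it; the residual
#' two-base set decides the class). Sites with three or more bases are counted
#' as multistate and excluded from the ts/tv denominator. Percentages are
#' reported rounded to the nearest integer (half away from zero); exact values
#' are kept alongside. With zero ts+tv sites the percentages are `NA`
#' (undefined, not 0).
#'
#' @param sites Result of [profile_variable_sites()].
#' @param group Group label.
#' @return List (class `rd_spectrum`) with fields `group`,
#'   `n_variable_sites`, `n_dimorphic`, `n_transition_sites`,
#'   `n_transversion_sites`, `n_multistate_sites`, `n_indel_sites`,
#'   `pct_transitions`, `pct_TC_among_transitions` and their `_exact`
#'   companions.
#' @export
substitution_spectrum <- function(sites, group) {
  scol <- paste0("states_", group)
  if (!scol %in% names(sites)) stop("no such group in profile: ", group)
  stl <- strsplit(sites[[scol]], "/", fixed = TRUE)
  n_var <- 0L; n_ts <- 0L; n_tv <- 0L; n_multi <- 0L; n_indel <- 0L
  n_dimorphic <- 0L; n_tc <- 0L
  for (st in stl) {
    if (length(unique(st)) < 2) next       # invariant within this group
    n_var <- n_var + 1L
    cl <- classify_substitution(st)
    if (cl$indel) n_indel <- n_indel + 1L
    bases <- setdiff(unique(ifelse(st == "U", "T", st)), "-")
    if (length(bases) == 2 && !cl$indel) n_dimorphic <- n_dimorphic + 1L
    if (cl$class == "transition") {
      n_ts <- n_ts + 1L
      if (setequal(bases, c("C", "T"))) n_tc <- n_tc + 1L
    } else if (cl$class == "transversion") {
      n_tv <- n_tv + 1L
    } else if (cl$class == "multistate") {
      n_multi <- n_multi + 1L
    }
  }
  pct_ts_exact <- if (n_ts + n_tv > 0) 100 * n_ts / (n_ts + n_tv) else NA_real_
  pct_tc_exact <- if (n_ts > 0) 100 * n_tc / n_ts else
    if (n_ts + n_tv > 0) 0 else NA_real_
  structure(list(
    group = group,
    n_variable_sites = n_var,
    n_dimorphic = n_dimorphic,
    n_transition_sites = n_ts,
    n_transversion_sites = n_tv,
    n_multistate_sites = n_multi,
    n_indel_sites = n_indel,
    pct_transitions = if (is.na(pct_ts_exact)) NA_real_ else
      round_half_away(pct_ts_exact),
    pct_TC_among_transitions = if (is.na(pct_tc_exact)) NA_real_ else
      round_half_away(pct_tc_exact),
    pct_transitions_exact = pct_ts_exact,
    pct_TC_among_transitions_exact = pct_tc_exact
  ), class = "rd_spectrum")
}

#' Detect clustered variable regions
#'
#' Maximal runs of variable positions in which consecutive members differ by
#' at most `max_gap` positions; runs with fewer than `min_sites` members are
#' suppressed. Labels `VR1`, `VR2`, ... are assigned in positional order.
#'
#' @param sites [profile_variable_sites()] result (or integer positions).
#' @param max_gap Maximum spacing between consecutive member positions.
#' @param min_sites Minimum number of members for a reported region.
#' @return Data frame with `label`, `start`, `end`, `n_sites`,
#'   `member_positions` (comma-joined).
#' @export
detect_variable_regions <- function(sites, max_gap = 5L, min_sites = 3L) {
  pos <- if (is.data.frame(sites)) sites$position else as.integer(sites)
  pos <- sort(unique(pos))
  empty <- data.frame(label = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      member_positions = character(0))
  if (length(pos) == 0) return(empty)
  run_id <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
  runs <- split(pos, run_id)
  runs <- runs[vapply(runs, length, integer(1)) >= min_sites]
  if (length(runs) == 0) return(empty)
  out <- data.frame(
    label = paste0("VR", seq_along(runs)),
    start = vapply(runs, min, integer(1)),
    end = vapply(runs, max, integer(1)),
    n_sites = vapply(runs, length, integer(1)),
    member_positions = vapply(runs, paste, character(1), collapse = ","),
    row.names = NULL
  )
  out
}

#' Variable sites inside a fixed window
#'
#' The canonical variable regions used in reports are fixed windows (defaults
#' 154-172 and 432-452); this helper subsets a profile to one window.
#'
#' @param sites [profile_variable_sites()] result.
#' @param start,end Window bounds (reference positions, inclusive).
#' @return Integer vector of member positions.
#' @export
sites_in_window <- function(sites, start, end) {
  sites$position[sites$position >= start & sites$position <= end]
}

#' Reconcile an ambiguity-coded consensus against the clone pool
#'
#' For every ambiguous IUPAC symbol of the consensus the verdict is
#' `consistent` when the set of bases observed among the clones at that
#' position is covered by the symbol's expansion and at least two bases are
#' observed; `inconsistent` when an observed base falls outside the
#' expansion; `uninformative` when the clones show fewer than two bases
#' there. Unambiguous consensus characters at clone-variable sites are also
#' reported (verdict `uninformative`) with a note on whether the consensus
#' base occurs among the clone states.
#'
#' @param consensus Single named sequence (character vector of length 1,
#'   aligned to `aln`'s coordinates: same column count).
#' @param sites [profile_variable_sites()] result for the clone alignment.
#' @param aln Clone [rd_alignment()].
#' @param clone_ids Which records of `aln` form the comparison pool
#'   (default: all).
#' @return Data frame with `position`, `symbol`, `expansion`, `observed`,
#'   `verdict`, `note`.
#' @export
check_ambiguity_consistency <- function(consensus, sites, aln,
                                        clone_ids = names(aln$seqs)) {
  cons <- toupper(consensus[[1]])
  if (nchar(cons) != n_columns(aln))
    stop("consensus length ", nchar(cons), " != alignment columns ",
         n_columns(aln))
  m <- aln_matrix(aln)[clone_ids, , drop = FALSE]
  cc <- strsplit(cons, "")[[1]]
  rows <- list()
  for (j in seq_along(cc)) {
    sym <- cc[j]
    exp <- iupac_expand(sym)
    ambiguous <- length(exp) >= 2
    pos <- column_position(aln, j)
    clone_bases <- setdiff(site_states(m[, j]), "-")
    clone_bases <- unique(ifelse(clone_bases == "U", "T", clone_bases))
    variable_here <- pos %in% sites$position
    if (!ambiguous && !variable_here) next
    if (ambiguous) {
      verdict <- if (!all(clone_bases %in% exp)) "inconsistent"
                 else if (length(clone_bases) >= 2) "consistent"
                 else "uninformative"
      note <- ""
    } else {
      verdict <- "uninformative"
      note <- if (sym %in% clone_bases)
        "unambiguous; base occurs among clone states"
      else "unambiguous; base absent from clone states"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      position = pos, symbol = sym,
      expansion = paste(exp, collapse = "/"),
      observed = paste(clone_bases, collapse = "/"),
      verdict = verdict, note = note, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(position = integer(0), symbol = character(0),
                      expansion = character(0), observed = character(0),
                      verdict = character(0), note = character(0)))
  do.call(rbind, rows)
}

#' Per-column character counts for a window (sequence-logo matrix)
#'
#' @param aln An [rd_alignment()].
#' @param start,end Window bounds in reference positions.
#' @return Integer matrix, rows = characters observed, columns named by reference
#'   position; column sums equal the record count.
#' @export
position_frequency_matrix <- function(aln, start, end) {
  cols <- position_column(aln, start:end)
  m <- aln_matrix(aln)[, cols, drop = FALSE]
  chars <- sort(unique(as.vector(m)))
  out <- vapply(seq_len(ncol(m)), function(j)
    vapply(chars, function(ch) sum(m[, j] == ch), integer(1)),
    integer(length(chars)))
  out <- matrix(out, nrow = length(chars),
                dimnames = list(chars, start:end))
  out
}

#' Pairwise substitution and indel differences
#'
#' Substitution differences count columns where two records carry different
#' non-gap characters; gap-versus-base columns are counted separately as
#' indel differences. Identical pairs have zero of both.
#'
#' @param aln An [rd_alignment()].
#' @param ids Record subset (default all).
#' @return List (class `rd_pairwise`): `subst` and `indel` symmetric integer
#'   matrices, `identical_pairs` data frame, `max_subst`, and
#'   `max_pct` = 100 * max_subst / alignment length.
#' @export
pairwise_differences <- function(aln, ids = names(aln$seqs)) {
  m <- aln_matrix(aln)[ids, , drop = FALSE]
  k <- nrow(m)
  subst <- matrix(0L, k, k, dimnames = list(ids, ids))
  indel <- matrix(0L, k, k, dimnames = list(ids, ids))
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      a <- m[i, ]; b <- m[j, ]
      gap_a <- a == "-"; gap_b <- b == "-"
      s <- sum(!gap_a & !gap_b & a != b)
      g <- sum(xor(gap_a, gap_b))
      subst[i, j] <- subst[j, i] <- s
      indel[i, j] <- indel[j, i] <- g
    }
  }
  tot <- subst + indel
  idp <- which(upper.tri(tot) & tot == 0, arr.ind = TRUE)
  identical_pairs <- data.frame(id1 = ids[idp[, 1]], id2 = ids[idp[, 2]],
                                stringsAsFactors = FALSE)
  structure(list(subst = subst, indel = indel,
                 identical_pairs = identical_pairs,
                 max_subst = if (k >= 2) max(subst) else 0L,
                 max_pct = if (k >= 2) 100 * max(subst) / ncol(m) else 0),
            class = "rd_pairwise")
}
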