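PAIR_SCORES_DEFAULT <- c(GC = 3, AU = 2, GU = 1)

#' Can two bases pair in an RNA helix?
#'
#' Allowed pairs are the canonical A:U and G:C plus the G:U wobble (symmetric);
#' T is read as U. No other non-canonical pairs are admitted.
#'
#' @param a,b Single characters.
#' @return Logical.
#' @export
can_pair <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  a <- ifelse(a == "T", "U", a); b <- ifelse(b == "T", "U", b)
  key <- paste0(pmin(a, b), pmax(a, b))
  key %in% c("AU", "CG", "GU")
}

pair_score <- function(a, b, scores = PAIR_SCORES_DEFAULT) {
  a <- toupper(a); b <- toupper(b)
  a <- ifelse(a == "T", "U", a); b <- ifelse(b == "T", "U", b)
  key <- paste0(pmin(a, b), pmax(a, b))
  key[key == "CG"] <- "GC"
  out <- scores[key]
  out[is.na(out)] <- -Inf
  unname(out)
}

new_pair_table <- function(partner, offset = 1L) {
  partner <- as.integer(partner)
  n <- length(partner)
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j != 0L) {
      if (j < 1L || j > n || j == i || partner[j] != i)
        stop("partner array is not reciprocal at position ", i)
    }
  }
  structure(list(length = n, partner = partner, offset = as.integer(offset)),
            class = "rd_pair_table")
}

#' @export
print.rd_pair_table <- function(x, ...) {
  cat(sprintf("rd_pair_table: %d nt, %d pairs (offset %d)\n",
              x$length, sum(x$partner > 0) / 2, x$offset))
  invisible(x)
}

#' Pair list of a pair table
#' @param pt `rd_pair_table`.
#' @param absolute Use reference coordinates (add offset)?
#' @return Two-column integer matrix (i < j).
#' @export
pair_list <- function(pt, absolute = FALSE) {
  i <- which(pt$partner > seq_len(pt$length))
  m <- cbind(i = i, j = pt$partner[i])
  if (absolute) m <- m + pt$offset - 1L
  m
}

#' Fold a sequence by base-pair score maximization
#'
#' Nussinov-style dynamic programming: finds the nested (pseudoknot-free)
#' structure maximizing the summed pair scores (defaults G:C = 3, A:U = 2,
#' G:U = 1) subject to hairpin loops of at least `min_loop` unpaired
#' positions. This is a topology-level simplification of thermodynamic
#' free-energy folding: conclusions that depend only on which positions sit
#' in stems versus loops are preserved, stacking energetics are not.
#' Traceback is deterministic: closing the pair (i,j) is preferred over
#' bifurcation, and bifurcation points are taken at the smallest split.
#'
#' @param seq Nucleotide string over A/C/G/T/U.
#' @param min_loop Minimum hairpin loop size (default 3).
#' @param scores Named vector of pair scores (`GC`, `AU`, `GU`).
#' @param offset Reference position of the first base.
#' @return An `rd_pair_table`.
#' @export
fold_maxpair <- function(seq, min_loop = 3L, scores = PAIR_SCORES_DEFAULT,
                         offset = 1L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[chars == "T"] <- "U"
  if (!all(chars %in% c("A", "C", "G", "U")))
    stop("fold_maxpair: sequence must be over A/C/G/T/U")
  n <- length(chars)
  partner <- integer(n)
  if (n >= min_loop + 2L) {
    S <- matrix(0, n, n)
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- S[i + 1, j - 1] + pair_score(chars[i], chars[j], scores)
        best <- max(best, S[i + 1, j], S[i, j - 1])
        if (j - i >= 2)
          for (k in i:(j - 1)) {
            v <- S[i, k] + S[k + 1, j]
            if (v > best) best <- v
          }
        S[i, j] <- best
      }
    }
    # deterministic traceback
    stack <- list(c(1L, n))
    while (length(stack) > 0) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (i >= j || j - i <= min_loop) next
      sc <- pair_score(chars[i], chars[j], scores)
      inner <- if (i + 1 <= j - 1) S[i + 1, j - 1] else 0
      if (is.finite(sc) && S[i, j] == inner + sc) {
        partner[i] <- j; partner[j] <- i
        stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
      } else if (S[i, j] == S[i + 1, j]) {
        stack[[length(stack) + 1L]] <- c(i + 1L, j)
      } else if (S[i, j] == S[i, j - 1]) {
        stack[[length(stack) + 1L]] <- c(i, j - 1L)
      } else {
        for (k in i:(j - 1)) {
          if (S[i, j] == S[i, k] + S[k + 1, j]) {
            stack[[length(stack) + 1L]] <- c(i, k)
            stack[[length(stack) + 1L]] <- c(k + 1L, j)
            break
          }
        }
      }
    }
  }
  new_pair_table(partner, offset = offset)
}

#' Parse a dot-bracket string
#'
#' @param s String over `.`, `(`, `)`.
#' @param offset Reference position of the first character.
#' @return An `rd_pair_table`.
#' @export
parse_dot_bracket <- function(s, offset = 1L) {
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad) > 0)
    stop("illegal dot-bracket character at position ", bad[1])
  partner <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (length(stack) == 0)
        stop("unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack) > 0)
    stop("unbalanced '(' at position ", stack[length(stack)])
  new_pair_table(partner, offset = offset)
}

#' Write a pair table as dot-bracket
#' @param pt `rd_pair_table`.
#' @return String.
#' @export
write_dot_bracket <- function(pt) {
  out <- rep(".", pt$length)
  i <- which(pt$partner > seq_len(pt$length))
  out[i] <- "("
  out[pt$partner[i]] <- ")"
  paste(out, collapse = "")
}

# is position p (unpaired) enclosed by any pair i<p<j?
enclosed_by_pair <- function(pt, p) {
  pl <- pair_list(pt)
  any(pl[, 1] < p & pl[, 2] > p)
}

#' Map variable sites into stem/loop context
#'
#' Roles: `stem_backfold` for paired sites on the 3' strand (position greater
#' than its partner), `stem_forward` for the 5' strand, `loop` for unpaired
#' sites enclosed by at least one pair, `unpaired_other` otherwise. Partner
#' states are taken from the sites profile when the partner is itself
#' variable, else from the (invariant) alignment column.
#'
#' @param pt `rd_pair_table` whose offset places it in reference coordinates.
#' @param sites [profile_variable_sites()] result.
#' @param aln The clone [rd_alignment()] (for invariant partner bases).
#' @return Data frame with `position`, `role`, `partner_position`,
#'   `partner_states`, `partner_variable`.
#' @export
map_site_context <- function(pt, sites, aln) {
  win <- pt$offset + seq_len(pt$length) - 1L
  inside <- sites$position >= min(win) & sites$position <= max(win)
  if (!any(inside)) {
    return(data.frame(position = integer(0), role = character(0),
                      partner_position = integer(0),
                      partner_states = character(0),
                      partner_variable = logical(0)))
  }
  m <- aln_matrix(aln)
  rows <- lapply(sites$position[inside], function(p) {
    local <- p - pt$offset + 1L
    q <- pt$partner[local]
    if (q == 0L) {
      role <- if (enclosed_by_pair(pt, local)) "loop" else "unpaired_other"
      data.frame(position = p, role = role,
                 partner_position = NA_integer_,
                 partner_states = NA_character_,
                 partner_variable = NA, stringsAsFactors = FALSE)
    } else {
      qpos <- q + pt$offset - 1L
      role <- if (local > q) "stem_backfold" else "stem_forward"
      if (qpos %in% sites$position) {
        pstates <- sites$pooled_states[sites$position == qpos]
        pvar <- TRUE
      } else {
        col <- m[, position_column(aln, qpos)]
        pstates <- paste(site_states(col), collapse = "/")
        pvar <- FALSE
      }
      data.frame(position = p, role = role, partner_position = qpos,
                 partner_states = pstates, partner_variable = pvar,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Classify the structural effect of a variable site
#'
#' Decision order for stem sites: a gap among the site or partner states
#' makes the call `indeterminate`; when every observed state pairs
#' (canonically or G:U) with every partner state the site is
#' `wobble_neutral`; otherwise, when the partner is itself variable and at
#' least one joint state combination restores pairing it is
#' `compensatory`; a forward-strand (5') stem
#' site with an invariant partner that is not wobble-neutral is
#' `forward_strand_variant`; anything else paired is `disruptive`. Unpaired
#' sites are `loop_variant` (the role distinguishes hairpin loops from other
#' unpaired context).
#'
#' @param site_states Character vector (or `/`-joined string) of the site's
#'   observed states.
#' @param ctx One row of [map_site_context()].
#' @return List with `position`, `effect`, `role`, `details`.
#' @export
classify_structural_effect <- function(site_states, ctx) {
  if (length(site_states) == 1 && grepl("/", site_states))
    site_states <- strsplit(site_states, "/", fixed = TRUE)[[1]]
  st <- unique(toupper(site_states))
  role <- ctx$role
  if (role %in% c("loop", "unpaired_other")) {
    return(list(position = ctx$position, effect = "loop_variant", role = role,
                details = paste(st, collapse = "/")))
  }
  pstates <- strsplit(ctx$partner_states, "/", fixed = TRUE)[[1]]
  details <- sprintf("%s ~ %s (partner %d)",
                     paste(st, collapse = "/"),
                     paste(pstates, collapse = "/"), ctx$partner_position)
  if ("-" %in% st || "-" %in% pstates) {
    return(list(position = ctx$position, effect = "indeterminate",
                role = role, details = details))
  }
  joint_ok <- outer(st, pstates, Vectorize(can_pair))
  effect <-
    if (all(joint_ok)) "wobble_neutral"
    else if (isTRUE(ctx$partner_variable) && any(joint_ok)) "compensatory"
    else if (role == "stem_forward") "forward_strand_variant"
    else "disruptive"
  list(position = ctx$position, effect = effect, role = role,
       details = details)
}

#' Structural-effect table for all mapped sites
#'
#' @param pt `rd_pair_table` in reference coordinates.
#' @param sites [profile_variable_sites()] result.
#' @param aln Clone [rd_alignment()].
#' @return Data frame with `position`, `role`, `partner_position`, `effect`,
#'   `details`.
#' @export
structural_effects <- function(pt, sites, aln) {
  ctx <- map_site_context(pt, sites, aln)
  if (nrow(ctx) == 0) return(cbind(ctx, effect = character(0)))
  rows <- lapply(seq_len(nrow(ctx)), function(i) {
    p <- ctx$position[i]
    eff <- classify_structural_effect(
      sites$pooled_states[sites$position == p], ctx[i, ])
    data.frame(position = p, role = ctx$role[i],
               partner_position = ctx$partner_position[i],
               effect = eff$effect, details = eff$details,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Compensatory-type catalogs for the two variable regions.
# VR1 is diagnosed by positions (103, 159); VR2 by the triplets at
# (389, 390, 391) and (443, 442, 441). Type V of VR1 matches only
# ambiguity-coded consensus records, never clones.
VR1_TYPES <- data.frame(
  type = c("I", "II", "III", "IV"),
  p103 = c("A", "G", "A", "G"),
  p159 = c("T", "T", "C", "C"),
  stringsAsFactors = FALSE
)
VR2_TYPES <- data.frame(
  type = c("I", "II", "III", "IV", "V", "VI"),
  t389_391 = c("AAA", "AAA", "AAA", "AAA", "GAG", "GAG"),
  t443_441 = c("TTT", "CTT", "TTC", "CTC", "CTC", "CTT"),
  stringsAsFactors = FALSE
)

VR1_DIAGNOSTIC_POSITIONS <- c(103L, 159L)
VR2_DIAGNOSTIC_POSITIONS_5P <- c(389L, 390L, 391L)
VR2_DIAGNOSTIC_POSITIONS_3P <- c(443L, 442L, 441L)

#' Assign a compensatory substitution type
#'
#' Exact lookup of the states observed at the diagnostic positions against
#' the region's catalog. For VR1 the diagnostic positions are 103 and 159;
#' an ambiguity symbol (R or N) at 103 with T at 159 is the consensus-only
#' type V and is matched only when `is_consensus = TRUE`. For VR2 the
#' diagnostics are the triplets at 389-390-391 (5' strand) and 443-442-441
#' (3' strand, in that order). Combinations absent from the catalog are
#' `"novel"`.
#'
#' @param clone_states Character vector of states at the diagnostic
#'   positions: length 2 (VR1: states at 103, 159) or length 6 (VR2: states
#'   at 389, 390, 391, 443, 442, 441).
#' @param region `"VR1"` or `"VR2"`.
#' @param clone_id Label carried through to the result.
#' @param is_consensus Is this an ambiguity-coded database consensus record?
#' @return List (class `rd_comp_assignment`) with `clone_id`, `region`,
#'   `observed_states`, `type_label`.
#' @export
assign_compensatory_type <- function(clone_states, region,
                                     clone_id = NA_character_,
                                     is_consensus = FALSE) {
  clone_states <- toupper(clone_states)
  if ("-" %in% clone_states)
    stop("gap at a diagnostic position for ", clone_id)
  region <- match.arg(region, c("VR1", "VR2"))
  if (region == "VR1") {
    if (length(clone_states) != 2)
      stop("VR1 typing needs states at positions 103 and 159")
    hit <- VR1_TYPES$type[VR1_TYPES$p103 == clone_states[1] &
                          VR1_TYPES$p159 == clone_states[2]]
    label <- if (length(hit) == 1) hit
      else if (is_consensus && clone_states[1] %in% c("R", "N") &&
               clone_states[2] == "T") "V"
      else "novel"
  } else {
    if (length(clone_states) != 6)
      stop("VR2 typing needs states at 389,390,391 and 443,442,441")
    t5 <- paste(clone_states[1:3], collapse = "")
    t3 <- paste(clone_states[4:6], collapse = "")
    hit <- VR2_TYPES$type[VR2_TYPES$t389_391 == t5 &
                          VR2_TYPES$t443_441 == t3]
    label <- if (length(hit) == 1) hit else "novel"
  }
  structure(list(clone_id = clone_id, region = region,
                 observed_states = clone_states, type_label = label),
            class = "rd_comp_assignment")
}

#' Compensatory types for every record of an alignment
#'
#' @param aln An [rd_alignment()] covering the diagnostic positions.
#' @param ids Records to type (default all).
#' @param consensus_ids Records treated as ambiguity-coded consensus entries.
#' @return Data frame with `clone_id`, `region`, `observed_states`,
#'   `type_label` (two rows per record: VR1 and VR2).
#' @export
compensatory_type_table <- function(aln, ids = names(aln$seqs),
                                    consensus_ids = character(0)) {
  m <- aln_matrix(aln)
  rows <- list()
  for (id in ids) {
    is_cons <- id %in% consensus_ids
    vr1 <- m[id, position_column(aln, VR1_DIAGNOSTIC_POSITIONS)]
    a1 <- assign_compensatory_type(vr1, "VR1", id, is_cons)
    vr2 <- m[id, position_column(aln, c(VR2_DIAGNOSTIC_POSITIONS_5P,
                                        VR2_DIAGNOSTIC_POSITIONS_3P))]
    a2 <- assign_compensatory_type(vr2, "VR2", id, is_cons)
    rows[[length(rows) + 1L]] <- data.frame(
      clone_id = id, region = c("VR1", "VR2"),
      observed_states = c(paste(a1$observed_states, collapse = ""),
                          paste0(paste(a2$observed_states[1:3], collapse = ""),
                                 "/",
                                 paste(a2$observed_states[4:6], collapse = ""))),
      type_label = c(a1$type_label, a2$type_label), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Count intact diagnostic base pairs of a compensatory assignment
#'
#' VR1 has one diagnostic pair (103-159); VR2 has three (389-443, 390-442,
#' 391-441). A pair is intact when its joint states form A:U, G:C or G:U.
#'
#' @param assignment An `rd_comp_assignment`.
#' @return Integer count of intact pairs.
#' @export
pairing_integrity <- function(assignment) {
  st <- assignment$observed_states
  if (assignment$region == "VR1") {
    pairs <- list(c(st[1], st[2]))
  } else {
    pairs <- list(c(st[1], st[4]), c(st[2], st[5]), c(st[3], st[6]))
  }
  sum(vapply(pairs, function(p) can_pair(p[1], p[2]), logical(1)))
}

#' Intact diagnostic pairs per clone across both variable regions
#'
#' Sums [pairing_integrity()] over the VR1 pair (103-159) and the three VR2
#' pairs (389-443, 390-442, 391-441) for each record.
#'
#' @param aln An [rd_alignment()].
#' @param ids Records to evaluate (default all).
#' @return Named integer vector (max 4 per clone).
#' @export
clone_pairing_integrity <- function(aln, ids = names(aln$seqs)) {
  m <- aln_matrix(aln)
  out <- vapply(ids, function(id) {
    a1 <- assign_compensatory_type(
      m[id, position_column(aln, VR1_DIAGNOSTIC_POSITIONS)], "VR1", id)
    a2 <- assign_compensatory_type(
      m[id, position_column(aln, c(VR2_DIAGNOSTIC_POSITIONS_5P,
                                   VR2_DIAGNOSTIC_POSITIONS_3P))], "VR2", id)
    pairing_integrity(a1) + pairing_integrity(a2)
  }, integer(1))
  out
}
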