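#' Default hairpin specification for simulated repeats
#'
#' Two stem-loops mimicking the geometry observed in yeast D1/D2 domains: a
#' short hairpin whose 3' (back-folding) strand covers one variable region
#' and carries a diagnostic compensatory pair at the (103, 159)-style offset,
#' and a longer hairpin with a 3-bp diagnostic block. Each row pairs position
#' `pos5` with `pos3`.
#'
#' @param repeat_length Total repeat length the stems must fit into.
#' @return Data frame with columns `pos5`, `pos3`, `helix`.
#' @export
default_hairpin_spec <- function(repeat_length = 499L) {
  spec <- rbind(
    data.frame(pos5 = 90:97, pos3 = 172:165, helix = "D1.H1"),
    data.frame(pos5 = 98:108, pos3 = 164:154, helix = "D1.H2"),
    data.frame(pos5 = 380:384, pos3 = 452:448, helix = "D2.H4"),
    data.frame(pos5 = 385:391, pos3 = 447:441, helix = "D2.H3"),
    data.frame(pos5 = 404:412, pos3 = 440:432, helix = "D2.H5")
  )
  if (max(spec$pos3) > repeat_length)
    stop("hairpin spec does not fit into repeat_length")
  spec
}

hairpin_partner_vector <- function(hairpin_spec, repeat_length) {
  partner <- integer(repeat_length)
  partner[hairpin_spec$pos5] <- hairpin_spec$pos3
  partner[hairpin_spec$pos3] <- hairpin_spec$pos5
  partner
}

#' Simulation configuration for an rDNA repeat array
#'
#' Defaults emulate a ~0.5 kb repeat unit whose variation concentrates in the
#' back-folding 3' strands of two hairpins, with a transition-biased spectrum
#' (extra weight on C<->T opposite a partner G), occasional compensatory
#' co-mutation of the stem partner, and optional reticulate events
#' (recombination, gene conversion) on top of duplication-driven spread.
#'
#' @param repeat_length Repeat unit length in nt.
#' @param n_repeats Number of repeats in the array.
#' @param hairpin_spec Paired-coordinate data frame, see
#'   [default_hairpin_spec()].
#' @param mu Baseline per-site per-generation substitution probability.
#' @param hot_multiplier Rate multiplier for sites on the 3' back-folding
#'   strands (concentrates variation in the two variable regions).
#' @param ts_bias Probability a substitution is a transition.
#' @param tc_opposite_g_bias Extra multiplier on the transition weight at
#'   stem sites whose partner is G and whose current base is C or T.
#' @param comp_comutation_p Probability a pairing-breaking stem substitution
#'   is immediately accompanied by the restoring partner substitution.
#' @param rec_rate Expected recombination (suffix crossover) events per
#'   generation.
#' @param conv_rate Expected gene-conversion events per generation.
#' @param conv_tract_mean Mean conversion tract length (geometric).
#' @param dup_rate Expected duplication events (one repeat overwritten by a
#'   copy of another) per generation.
#' @param homogenization_p Per-generation probability that a site carrying a
#'   minority allele is overwritten by the column majority.
#' @param wobble_fraction Fraction of stem positions seeded as G:T wobble
#'   pairs in the master sequence.
#' @param n_generations Number of generations to evolve.
#' @param seed RNG seed (mandatory at [evolve_array()] time).
#' @return List of class `rd_sim_config`.
#' @export
sim_config <- function(repeat_length = 499L, n_repeats = 20L,
                       hairpin_spec = default_hairpin_spec(repeat_length),
                       mu = 1e-4, hot_multiplier = 25,
                       ts_bias = 0.8, tc_opposite_g_bias = 3,
                       comp_comutation_p = 0.5,
                       rec_rate = 0, conv_rate = 0, conv_tract_mean = 50,
                       dup_rate = 1, homogenization_p = 0,
                       wobble_fraction = 0.1,
                       n_generations = 100L, seed = NULL) {
  probs <- c(mu = mu, ts_bias = ts_bias,
             comp_comutation_p = comp_comutation_p,
             homogenization_p = homogenization_p,
             wobble_fraction = wobble_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(c(rec_rate, conv_rate, dup_rate) < 0))
    stop("event rates must be non-negative")
  if (any(hairpin_spec$pos5 > repeat_length) ||
      any(hairpin_spec$pos3 > repeat_length) ||
      any(hairpin_spec$pos5 < 1) || any(hairpin_spec$pos3 < 1))
    stop("hairpin spec outside repeat")
  if (any(duplicated(c(hairpin_spec$pos5, hairpin_spec$pos3))))
    stop("hairpin stem ranges overlap")
  structure(list(
    repeat_length = as.integer(repeat_length),
    n_repeats = as.integer(n_repeats),
    hairpin_spec = hairpin_spec,
    mu = mu, hot_multiplier = hot_multiplier, ts_bias = ts_bias,
    tc_opposite_g_bias = tc_opposite_g_bias,
    comp_comutation_p = comp_comutation_p,
    rec_rate = rec_rate, conv_rate = conv_rate,
    conv_tract_mean = conv_tract_mean, dup_rate = dup_rate,
    homogenization_p = homogenization_p,
    wobble_fraction = wobble_fraction,
    n_generations = as.integer(n_generations), seed = seed
  ), class = "rd_sim_config")
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))
WC_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Generate a master repeat consistent with a hairpin spec
#'
#' Random seeded sequence whose stem blocks are reverse-complementary under
#' A:T / G:C, with a configurable fraction of stem positions seeded as G:T
#' wobble pairs; all other positions are uniform random bases.
#'
#' @param config An `rd_sim_config`.
#' @return List: `seq` (character string) and `pair_table`
#'   (`rd_pair_table` over the full repeat, offset 1).
#' @export
make_master <- function(config) {
  L <- config$repeat_length
  spec <- config$hairpin_spec
  bases <- c("A", "C", "G", "T")
  seq <- sample(bases, L, replace = TRUE)
  for (r in seq_len(nrow(spec))) {
    p5 <- spec$pos5[r]; p3 <- spec$pos3[r]
    if (runif(1) < config$wobble_fraction) {
      seq[p5] <- "G"; seq[p3] <- "T"
    } else {
      seq[p5] <- sample(bases, 1)
      seq[p3] <- WC_COMPLEMENT[[seq[p5]]]
    }
  }
  pt <- new_pair_table(hairpin_partner_vector(spec, L), offset = 1L)
  list(seq = paste(seq, collapse = ""), pair_table = pt)
}

# site rate vector: baseline mu, multiplied on 3' back-folding strand sites
site_rates <- function(config) {
  r <- rep(config$mu, config$repeat_length)
  r[config$hairpin_spec$pos3] <- config$mu * config$hot_multiplier
  r
}

draw_substitution <- function(base, partner_base, config) {
  w_ts <- config$ts_bias
  if (!is.na(partner_base) && partner_base == "G" && base %in% c("C", "T"))
    w_ts <- w_ts * config$tc_opposite_g_bias
  p_ts <- w_ts / (w_ts + (1 - config$ts_bias))
  if (runif(1) < p_ts) TRANSITION_OF[[base]]
  else sample(TRANSVERSIONS_OF[[base]], 1)
}

truth_class <- function(new_base, partner_base, comutated) {
  if (is.na(partner_base)) return("loop")
  if (comutated) return("compensatory-pair")
  if (can_pair(new_base, partner_base)) "wobble-class" else "disruptive"
}

#' Evolve an rDNA repeat array
#'
#' Starts from `n_repeats` identical copies of a seeded master repeat and
#' applies, per generation and in this fixed order: duplications (a repeat
#' overwritten by a copy of another, the homogenization analog of repeat
#' turnover), substitutions (Poisson number of events placed proportionally
#' to site rates, transition-biased, C<->T further favoured opposite a
#' partner G, with probabilistic compensatory co-mutation of the stem
#' partner), recombination (suffix swap at a uniform breakpoint),
#' gene conversion (geometric tract copied between repeats), and per-site
#' majority homogenization. Every event is logged; replaying the log from
#' the master reproduces the array exactly.
#'
#' @param config An `rd_sim_config` with a non-NULL `seed`.
#' @return List of class `rd_sim_array`: `repeats` (character matrix
#'   n_repeats x L), `master`, `pair_table`, `events` (data frame),
#'   `truth` (one row per substitution event), `config`.
#' @export
evolve_array <- function(config) {
  if (is.null(config$seed)) stop("config$seed must be set")
  set.seed(config$seed)
  master <- make_master(config)
  L <- config$repeat_length
  n <- config$n_repeats
  partner <- master$pair_table$partner
  reps <- matrix(rep(strsplit(master$seq, "")[[1]], each = n), nrow = n)
  rates <- site_rates(config)
  total_rate <- n * sum(rates)
  ev <- list()
  log_event <- function(...) ev[[length(ev) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  truth <- list()
  for (gen in seq_len(config$n_generations)) {
    # 1. duplications
    for (k in seq_len(rpois(1, config$dup_rate))) {
      if (n < 2) break
      pick <- sample.int(n, 2)
      reps[pick[2], ] <- reps[pick[1], ]
      log_event(gen = gen, type = "duplication", rep1 = pick[1],
                rep2 = pick[2], site = NA, from = NA, to = NA,
                breakpoint = NA, tract_end = NA)
    }
    # 2. substitutions
    for (k in seq_len(rpois(1, total_rate))) {
      r <- sample.int(n, 1)
      s <- sample.int(L, 1, prob = rates)
      base <- reps[r, s]
      pbase <- if (partner[s] > 0) reps[r, partner[s]] else NA_character_
      newb <- draw_substitution(base, pbase, config)
      reps[r, s] <- newb
      log_event(gen = gen, type = "substitution", rep1 = r, rep2 = NA,
                site = s, from = base, to = newb, breakpoint = NA,
                tract_end = NA)
      comutated <- FALSE
      if (partner[s] > 0 && !can_pair(newb, pbase) &&
          runif(1) < config$comp_comutation_p) {
        restore <- WC_COMPLEMENT[[newb]]
        log_event(gen = gen, type = "substitution", rep1 = r, rep2 = NA,
                  site = partner[s], from = pbase, to = restore,
                  breakpoint = NA, tract_end = NA)
        reps[r, partner[s]] <- restore
        comutated <- TRUE
      }
      truth[[length(truth) + 1L]] <- data.frame(
        gen = gen, rep = r, site = s, to = newb,
        class = truth_class(newb, if (comutated)
          reps[r, partner[s]] else pbase, comutated),
        stringsAsFactors = FALSE)
    }
    # 3. recombination (suffix crossover between two repeats)
    for (k in seq_len(rpois(1, config$rec_rate))) {
      if (n < 2) break
      pick <- sample.int(n, 2)
      b <- sample.int(L - 1L, 1)
      tail1 <- reps[pick[1], (b + 1):L]
      reps[pick[1], (b + 1):L] <- reps[pick[2], (b + 1):L]
      reps[pick[2], (b + 1):L] <- tail1
      log_event(gen = gen, type = "recombination", rep1 = pick[1],
                rep2 = pick[2], site = NA, from = NA, to = NA,
                breakpoint = b, tract_end = NA)
    }
    # 4. gene conversion (donor tract copied onto acceptor)
    for (k in seq_len(rpois(1, config$conv_rate))) {
      if (n < 2) break
      pick <- sample.int(n, 2)
      start <- sample.int(L, 1)
      len <- rgeom(1, 1 / config$conv_tract_mean) + 1L
      end <- min(L, start + len - 1L)
      reps[pick[2], start:end] <- reps[pick[1], start:end]
      log_event(gen = gen, type = "conversion", rep1 = pick[1],
                rep2 = pick[2], site = start, from = NA, to = NA,
                breakpoint = NA, tract_end = end)
    }
    # 5. homogenization toward the column majority
    if (config$homogenization_p > 0) {
      for (s in seq_len(L)) {
        col <- reps[, s]
        tab <- table(col)
        if (length(tab) < 2) next
        maj <- names(tab)[which.max(tab)]
        minor <- which(col != maj)
        flip <- minor[runif(length(minor)) < config$homogenization_p]
        for (r in flip) {
          log_event(gen = gen, type = "homogenization", rep1 = r, rep2 = NA,
                    site = s, from = reps[r, s], to = maj, breakpoint = NA,
                    tract_end = NA)
          reps[r, s] <- maj
        }
      }
    }
  }
  events <- if (length(ev) > 0) do.call(rbind, ev) else
    data.frame(gen = integer(0), type = character(0), rep1 = integer(0),
               rep2 = integer(0), site = integer(0), from = character(0),
               to = character(0), breakpoint = integer(0),
               tract_end = integer(0))
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(gen = integer(0), rep = integer(0), site = integer(0),
               to = character(0), class = character(0))
  rownames(reps) <- sprintf("r%02d", seq_len(n))
  structure(list(repeats = reps, master = master$seq,
                 pair_table = master$pair_table, events = events,
                 truth = truth, config = config),
            class = "rd_sim_array")
}

#' Replay an event log from the master sequence
#'
#' Deterministically re-applies the logged events to an array of identical
#' master copies; the result must equal the simulated repeats byte for byte.
#'
#' @param array An `rd_sim_array`.
#' @return Character matrix of repeats.
#' @export
replay_events <- function(array) {
  cfg <- array$config
  L <- cfg$repeat_length
  n <- cfg$n_repeats
  reps <- matrix(rep(strsplit(array$master, "")[[1]], each = n), nrow = n)
  evs <- array$events
  for (i in seq_len(nrow(evs))) {
    e <- evs[i, ]
    switch(e$type,
      duplication = { reps[e$rep2, ] <- reps[e$rep1, ] },
      substitution = { reps[e$rep1, e$site] <- e$to },
      homogenization = { reps[e$rep1, e$site] <- e$to },
      recombination = {
        b <- e$breakpoint
        tail1 <- reps[e$rep1, (b + 1):L]
        reps[e$rep1, (b + 1):L] <- reps[e$rep2, (b + 1):L]
        reps[e$rep2, (b + 1):L] <- tail1
      },
      conversion = {
        reps[e$rep2, e$site:e$tract_end] <- reps[e$rep1, e$site:e$tract_end]
      },
      stop("unknown event type: ", e$type))
  }
  rownames(reps) <- rownames(array$repeats)
  reps
}

#' Sample clones from a simulated array
#'
#' Emulates random cloning of PCR-amplified repeats: `n` repeats drawn
#' uniformly with replacement.
#'
#' @param array An `rd_sim_array`.
#' @param n Number of clones.
#' @param seed RNG seed.
#' @param prefix Clone id prefix.
#' @return Named character vector of sequences (ids `<prefix>01`, ...).
#' @export
sample_clones <- function(array, n, seed, prefix = "clone") {
  if (nrow(array$repeats) == 0) stop("empty array")
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  pick <- sample.int(nrow(array$repeats), n, replace = TRUE)
  seqs <- apply(array$repeats[pick, , drop = FALSE], 1, paste, collapse = "")
  names(seqs) <- sprintf("%s%02d", prefix, seq_len(n))
  attr(seqs, "source_repeats") <- pick
  seqs
}

#' Ambiguity-coded consensus of a repeat pool
#'
#' Per column, the minimal IUPAC code covering all observed bases; a gap
#' anywhere in the column emits a gap (flagged via the `gap_columns`
#' attribute).
#'
#' @param repeats Character matrix (rows = repeats) or named character
#'   vector of equal-length sequences.
#' @param id Record id of the consensus.
#' @return Named character vector of length 1.
#' @export
emit_consensus_with_ambiguity <- function(repeats, id = "consensus") {
  if (is.matrix(repeats)) m <- repeats
  else {
    if (length(unique(nchar(repeats))) != 1)
      stop("repeats must have equal lengths")
    m <- do.call(rbind, strsplit(unname(repeats), ""))
  }
  if (nrow(m) < 1) stop("need at least one repeat")
  gap_cols <- integer(0)
  out <- vapply(seq_len(ncol(m)), function(j) {
    states <- unique(toupper(m[, j]))
    if ("-" %in% states) { gap_cols <<- c(gap_cols, j); return("-") }
    iupac_code(states)
  }, character(1))
  res <- stats::setNames(paste(out, collapse = ""), id)
  attr(res, "gap_columns") <- gap_cols
  res
}

#' Compare analysis output against simulator ground truth
#'
#' Site-level confusion between the variation profile's detected variable
#' positions and the positions truly mutated among the sampled repeats, the
#' modal structural-effect class among detected stem variants, and the Phi
#' verdict against the generative recombination rate.
#'
#' @param array An `rd_sim_array`.
#' @param clones Output of [sample_clones()].
#' @param sites [profile_variable_sites()] of the clones.
#' @param phi Optional `rd_phi_result` on the clones.
#' @param alpha Significance level for the Phi verdict.
#' @return List: `site_sensitivity`, `site_specificity`, `n_true_variable`,
#'   `effect_counts` (from the simulator truth for mutated stem sites),
#'   `phi_rejected`, `recombination_truth`.
#' @export
truth_evaluation <- function(array, clones, sites, phi = NULL,
                             alpha = 0.05) {
  src <- attr(clones, "source_repeats")
  if (is.null(src)) stop("clones lack source_repeats attribute (id mismatch)")
  sub <- array$repeats[src, , drop = FALSE]
  truly_variable <- which(apply(sub, 2, function(col)
    length(unique(col)) > 1))
  detected <- sites$position  # clone alignment offset is 1: positions = sites
  L <- array$config$repeat_length
  tp <- length(intersect(detected, truly_variable))
  fp <- length(setdiff(detected, truly_variable))
  fn <- length(setdiff(truly_variable, detected))
  tn <- L - tp - fp - fn
  stem_truth <- array$truth[array$truth$site %in% truly_variable, ]
  list(
    site_sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    site_specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n_true_variable = length(truly_variable),
    effect_counts = table(stem_truth$class),
    phi_rejected = if (!is.null(phi)) phi$p_value < alpha else NA,
    recombination_truth = array$config$rec_rate > 0
  )
}
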