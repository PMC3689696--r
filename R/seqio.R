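IUPAC_ALPHABET <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N", "-")

#' IUPAC ambiguity code expansions
#'
#' Returns the set of unambiguous bases denoted by a single IUPAC nucleotide
#' symbol. `U` expands to `"T"` (T and U are treated as the same state
#' throughout the package; the input letter is preserved on output).
#'
#' @param symbol Single character, one of the IUPAC nucleotide codes.
#' @return Character vector of bases from `{A, C, G, T}`; `character(0)` for
#'   the gap character.
#' @examples
#' iupac_expand("R")  # A G
#' iupac_expand("N")  # A C G T
#' @export
iupac_expand <- function(symbol) {
  map <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"), `-` = character(0)
  )
  out <- map[[toupper(symbol)]]
  if (is.null(out)) stop("not an IUPAC nucleotide symbol: ", symbol)
  out
}

#' Minimal IUPAC code covering a set of bases
#'
#' Inverse of [iupac_expand()]: the single symbol whose expansion equals the
#' given base set.
#'
#' @param bases Character vector over `{A, C, G, T}` (T/U equivalent).
#' @return Single IUPAC character.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(ifelse(toupper(bases) == "U", "T", toupper(bases))))
  if (length(bases) == 0) return("-")
  key <- paste(bases, collapse = "")
  map <- c(A = "A", C = "C", G = "G", T = "T",
           AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
           ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  out <- map[[key]]
  if (is.null(out)) stop("cannot encode base set: ", key)
  unname(out)
}

validate_seq <- function(seq, id = "?") {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% IUPAC_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("record '%s': illegal character '%s' at sequence position %d",
                 id, chars[bad[1]], bad[1]))
  }
  invisible(TRUE)
}

#' Construct an alignment object
#'
#' An alignment is a named character vector of equal-length upper-case IUPAC
#' sequences plus an `offset`: the reference position of column 1
#' (sites are numbered from the first nucleotide behind the forward
#' amplification primer). `"."` gap characters are normalized to `"-"`.
#'
#' @param seqs Named character vector (names = record ids, e.g. clone labels).
#' @param offset Integer >= 1, position of the first column.
#' @return An object of class `rd_alignment`.
#' @export
rd_alignment <- function(seqs, offset = 1L) {
  if (length(seqs) < 1) stop("alignment needs at least one record")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("records must carry unique ids")
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("records have unequal lengths: ", paste(unique(lens), collapse = ", "))
  if (lens[1] < 1) stop("alignment must have at least one column")
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1) stop("offset must be an integer >= 1")
  for (i in seq_along(seqs)) validate_seq(seqs[[i]], names(seqs)[i])
  structure(list(seqs = seqs, offset = offset), class = "rd_alignment")
}

#' @export
print.rd_alignment <- function(x, ...) {
  cat(sprintf("rd_alignment: %d records x %d columns (offset %d)\n",
              length(x$seqs), nchar(x$seqs[[1]]), x$offset))
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln An `rd_alignment`.
#' @return Integer.
#' @export
n_columns <- function(aln) nchar(aln$seqs[[1]])

#' Alignment as a character matrix
#'
#' @param aln An `rd_alignment`.
#' @return Character matrix, rows = records (rownames = ids), one column per
#'   alignment column.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- names(aln$seqs)
  m
}

#' Reference position of an alignment column
#'
#' Columns are numbered `offset, offset + 1, ...` so that reports use the
#' site-numbering convention of the source tables rather than raw indices.
#'
#' @param aln An `rd_alignment`.
#' @param column_index 1-based column index.
#' @return Integer reference position.
#' @export
column_position <- function(aln, column_index) {
  column_index <- as.integer(column_index)
  if (any(is.na(column_index)) || any(column_index < 1) ||
      any(column_index > n_columns(aln)))
    stop("column index out of range 1..", n_columns(aln))
  aln$offset + column_index - 1L
}

#' Alignment column index of a reference position
#' @param aln An `rd_alignment`.
#' @param position Reference coordinate(s).
#' @return Integer column index (errors if outside the alignment).
#' @export
position_column <- function(aln, position) {
  idx <- as.integer(position) - aln$offset + 1L
  if (any(idx < 1) || any(idx > n_columns(aln)))
    stop("position outside alignment window")
  idx
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences (U preserved).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) stop("duplicate record ids in ", path)
  for (i in seq_along(seqs)) validate_seq(seqs[[i]], names(seqs)[i])
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (or `rd_alignment`).
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rd_alignment")) seqs <- seqs$seqs
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a Clustal-format alignment
#'
#' Interleaved blocks are concatenated per record id; reconstructed sequences
#' must come out equal-length.
#'
#' @param path Clustal file (header line starting with CLUSTAL).
#' @param offset Reference position of column 1 (default 1).
#' @return An [rd_alignment()].
#' @export
read_clustal <- function(path, offset = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty Clustal file: ", path)
  if (!grepl("^CLUSTAL", lines[1], ignore.case = TRUE))
    stop("not a Clustal file (missing CLUSTAL header): ", path)
  body <- lines[-1]
  acc <- list()
  order <- character(0)
  for (ln in body) {
    if (grepl("^\\s*$", ln)) next
    # conservation lines contain only * : . and spaces
    if (grepl("^[\\s:.*]+$", ln, perl = TRUE)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.*\\-]+)\\s*\\d*\\s*$", ln))[[1]]
    if (length(m) != 3) stop("malformed Clustal line: ", ln)
    id <- m[2]
    if (!id %in% order) order <- c(order, id)
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], m[3])
  }
  if (length(acc) == 0) stop("Clustal file contains no sequence lines: ", path)
  seqs <- unlist(acc[order])
  if (length(unique(nchar(seqs))) != 1)
    stop("Clustal blocks reconstruct to unequal lengths")
  rd_alignment(seqs, offset = offset)
}

#' Write an alignment in Clustal format
#'
#' @param aln An `rd_alignment` (or named character vector of equal lengths).
#' @param path Output file.
#' @param width Residues per block line.
#' @export
write_clustal <- function(aln, path, width = 60L) {
  if (!inherits(aln, "rd_alignment")) aln <- rd_alignment(aln)
  seqs <- aln$seqs
  ids <- names(seqs)
  pad <- max(nchar(ids)) + 3L
  L <- n_columns(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL W multiple sequence alignment", con)
  writeLines("", con)
  m <- aln_matrix(aln)
  for (start in seq(1L, L, by = width)) {
    end <- min(start + width - 1L, L)
    for (id in ids) {
      writeLines(sprintf("%-*s%s", pad, id, substr(seqs[[id]], start, end)), con)
    }
    cons <- vapply(start:end, function(j)
      if (length(unique(m[, j])) == 1 && m[1, j] != "-") "*" else " ",
      character(1))
    writeLines(paste0(strrep(" ", pad), paste(cons, collapse = "")), con)
    writeLines("", con)
  }
  invisible(path)
}

# Needleman-Wunsch global alignment, linear gap penalty, deterministic
# traceback (diagonal preferred over up over left on score ties).
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  ai <- character(0); bi <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(av[i] == bv[j], match, mismatch)) {
      ai <- c(av[i], ai); bi <- c(bv[j], bi); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ai <- c(av[i], ai); bi <- c("-", bi); i <- i - 1
    } else {
      ai <- c("-", ai); bi <- c(bv[j], bi); j <- j - 1
    }
  }
  list(a = ai, b = bi, score = S[n + 1, m + 1])
}

edit_distance <- function(a, b) {
  # unit-cost Levenshtein via adist (base R)
  as.integer(utils::adist(a, b))
}

#' Center-star multiple alignment
#'
#' Lightweight aligner for sets of near-identical sequences (cloned repeats of
#' one array): the center is the record minimizing the summed pairwise edit
#' distance (ties broken by input order); every other record is aligned to the
#' center by global (Needleman-Wunsch) alignment and the pairwise gaps are
#' merged into one multiple alignment. Not a progressive aligner; for
#' substantially diverged inputs supply a pre-made alignment instead.
#'
#' @param seqs Named character vector, >= 2 ungapped sequences.
#' @param match,mismatch,gap Alignment scores (linear gap penalty).
#' @param offset Reference position of the first column of the result.
#' @return An [rd_alignment()].
#' @export
align_center_star <- function(seqs, match = 1, mismatch = -1, gap = -2,
                              offset = 1L) {
  if (length(seqs) < 2) stop("center-star alignment needs >= 2 records")
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("input sequences must be ungapped")
  seqs <- toupper(seqs)
  k <- length(seqs)
  dsum <- numeric(k)
  for (i in seq_len(k)) {
    dsum[i] <- sum(vapply(seq_len(k), function(j)
      if (i == j) 0L else edit_distance(seqs[[i]], seqs[[j]]), integer(1)))
  }
  center <- which.min(dsum)  # which.min takes the first on ties = input order
  cen <- seqs[[center]]
  others <- setdiff(seq_len(k), center)
  pw <- lapply(others, function(j) nw_align(cen, seqs[[j]], match, mismatch, gap))
  # merge: master gap pattern for the center = union of gaps inserted per pair
  # represented as number of inserted columns after each center residue
  ins <- matrix(0L, nrow = length(others), ncol = nchar(cen) + 1L)
  for (r in seq_along(pw)) {
    pos <- 0L
    for (ch in pw[[r]]$a) {
      if (ch == "-") ins[r, pos + 1L] <- ins[r, pos + 1L] + 1L else pos <- pos + 1L
    }
  }
  master_ins <- apply(ins, 2, max)
  ncol_out <- nchar(cen) + sum(master_ins)
  out <- matrix("-", nrow = k, ncol = ncol_out)
  # lay out the center
  cc <- strsplit(cen, "")[[1]]
  col <- master_ins[1]
  ccol <- integer(length(cc))  # output column of each center residue
  for (p in seq_along(cc)) {
    col <- col + 1L
    ccol[p] <- col
    col <- col + master_ins[p + 1L]
  }
  out[center, ccol] <- cc
  for (r in seq_along(pw)) {
    aa <- pw[[r]]$a; bb <- pw[[r]]$b
    pos <- 0L          # center residues consumed
    used_ins <- 0L     # insertions used in current slot
    for (t in seq_along(aa)) {
      if (aa[t] == "-") {
        used_ins <- used_ins + 1L
        slot_start <- if (pos == 0L) 0L else ccol[pos]
        out[others[r], slot_start + used_ins] <- bb[t]
      } else {
        pos <- pos + 1L
        used_ins <- 0L
        out[others[r], ccol[pos]] <- bb[t]
      }
    }
  }
  res <- apply(out, 1, paste, collapse = "")
  names(res) <- names(seqs)
  rd_alignment(res, offset = offset)
}

#' Trim terminal overhang columns
#'
#' Removes leading and trailing columns in which ALL of the reference records
#' carry gaps (database entries longer than the cloned amplicon leave such
#' overhangs after alignment). Internal reference gaps are kept. The offset is
#' updated so the first retained column keeps its reference position.
#'
#' @param aln An `rd_alignment`.
#' @param reference_ids Ids whose non-gap span defines the retained window.
#' @return Trimmed `rd_alignment`.
#' @export
trim_overhangs <- function(aln, reference_ids) {
  if (!all(reference_ids %in% names(aln$seqs)))
    stop("unknown reference ids: ",
         paste(setdiff(reference_ids, names(aln$seqs)), collapse = ", "))
  m <- aln_matrix(aln)[reference_ids, , drop = FALSE]
  covered <- colSums(m != "-") > 0
  if (!any(covered)) stop("trimming would remove every column")
  first <- which(covered)[1]
  last <- rev(which(covered))[1]
  seqs <- vapply(aln$seqs, substr, character(1), start = first, stop = last)
  rd_alignment(seqs, offset = aln$offset + first - 1L)
}
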