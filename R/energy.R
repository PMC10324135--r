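# Reduced nearest-neighbour RNA energetics: intermolecular duplex MFE by
# dynamic programming, intramolecular fold MFE (nested structures, stacking
# energy only), per-nucleotide normalisation, and exhaustive-enumeration
# oracles for small instances.
#
# The scoring model is deliberately small so every optimum is hand-checkable:
#   energy(duplex) = init + sum(stack terms over adjacent pairs)
#                  + loop_penalty * (unpaired nts between consecutive pairs,
#                    both strands)
#   energy(fold)   = sum(stack terms over stacked adjacent pairs); isolated
#                    pairs contribute 0; minimum hairpin loop of 3 unpaired nt.
# Pairs are Watson-Crick (GC, AU) or wobble (GU). An adapter taking the same
# sequences may substitute a full thermodynamic predictor behind the same
# signatures.

#' Reduced nearest-neighbour scoring table
#'
#' Stack energies are keyed by the unordered kind-pair of two adjacent base
#' pairs, with pair kinds GC, AU and GU; any stack involving a GU wobble gets
#' a single shallow value. Units are kcal/mol (kcal/mol/nt for the
#' interior-loop penalty, applied in the duplex model only).
#'
#' @param stack_gc_gc,stack_gc_au,stack_au_au Stack energies (<= 0).
#' @param stack_gu Stack energy for any stack involving a GU pair (<= 0).
#' @param init Helix initiation penalty (>= 0), charged once per duplex.
#' @param loop_penalty Per-nucleotide interior-loop penalty (>= 0).
#' @return An object of class `snohost_scoring`.
#' @export
scoring_table <- function(stack_gc_gc = -3.0, stack_gc_au = -2.0,
                          stack_au_au = -1.0, stack_gu = -0.5,
                          init = 4.0, loop_penalty = 0.5) {
  stopifnot(stack_gc_gc <= 0, stack_gc_au <= 0, stack_au_au <= 0,
            stack_gu <= 0, init >= 0, loop_penalty >= 0)
  structure(list(stack_gc_gc = stack_gc_gc, stack_gc_au = stack_gc_au,
                 stack_au_au = stack_au_au, stack_gu = stack_gu,
                 init = init, loop_penalty = loop_penalty),
            class = "snohost_scoring")
}

#' Read a scoring table from a YAML config
#'
#' Recognised keys are the arguments of [scoring_table()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return A `snohost_scoring` object.
#' @export
read_scoring_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg), names(formals(scoring_table)))]
  do.call(scoring_table, args)
}

# sequence sanitising: DNA accepted (T -> U), uppercased, alphabet-checked
clean_rna <- function(x, what = "sequence") {
  if (length(x) != 1 || is.na(x) || nchar(x) == 0) {
    stop(what, " must be a single non-empty string")
  }
  x <- chartr("tT", "uU", x)
  x <- toupper(x)
  if (grepl("[^ACGU]", x)) stop(what, " contains non-ACGU(T) characters")
  x
}

# base codes A=1, C=2, G=3, U=4
base_codes <- function(x) match(strsplit(x, "")[[1]], c("A", "C", "G", "U"))

# pair kind: 1 = GC, 2 = AU, 3 = GU, NA = not pairable (codes as above)
pair_kind_code <- function(a, b) {
  ifelse((a == 2 & b == 3) | (a == 3 & b == 2), 1L,
         ifelse((a == 1 & b == 4) | (a == 4 & b == 1), 2L,
                ifelse((a == 3 & b == 4) | (a == 4 & b == 3), 3L, NA_integer_)))
}

# 3x3 stack-energy lookup matrix indexed by pair-kind codes
stack_matrix <- function(table) {
  m <- matrix(table$stack_gu, 3, 3)
  m[1, 1] <- table$stack_gc_gc
  m[1, 2] <- m[2, 1] <- table$stack_gc_au
  m[2, 2] <- table$stack_au_au
  m
}

#' Intermolecular duplex minimum free energy
#'
#' Exact optimum of the reduced model over all co-linear pairings of `a`
#' (5'->3') with `b` (5'->3'): pair indices strictly increase in `a` and
#' strictly decrease in `b` (antiparallel duplex). If the optimum is >= 0 the
#' duplex is unfavourable and `mfe = 0` with an empty pairing is returned.
#'
#' @param a,b RNA sequences (character; T is read as U).
#' @param table A `snohost_scoring` table.
#' @return A list with `mfe` (kcal/mol, <= 0), `pairing` (two-column matrix of
#'   1-based indices into `a` and `b`, ordered by increasing `a` index), and
#'   `n_pairs`.
#' @examples
#' duplex_mfe("GGGG", "CCCC")$mfe   # 4 GC pairs, 3 GC/GC stacks: -5
#' @export
duplex_mfe <- function(a, b, table = scoring_table()) {
  a <- clean_rna(a, "a"); b <- clean_rna(b, "b")
  ca <- base_codes(a); cb <- base_codes(b)
  n <- length(ca); m <- length(cb)
  lp <- table$loop_penalty
  sm <- stack_matrix(table)

  kind <- outer(ca, cb, pair_kind_code)          # n x m, NA if unpairable
  dp <- matrix(Inf, n, m)                        # best energy ending at pair (i,j)
  ptr_i <- matrix(0L, n, m); ptr_j <- matrix(0L, n, m)
  # corner minima of g = dp - lp*i + lp*j over i' <= i, j' >= j, with argmin
  g_min <- matrix(Inf, n, m)
  g_arg_i <- matrix(0L, n, m); g_arg_j <- matrix(0L, n, m)

  for (i in seq_len(n)) {
    for (j in rev(seq_len(m))) {
      if (!is.na(kind[i, j])) {
        best <- 0; bi <- 0L; bj <- 0L      # start a new helix at (i, j)
        if (i > 1 && j < m) {
          if (!is.na(kind[i - 1, j + 1]) && is.finite(dp[i - 1, j + 1])) {
            cand <- dp[i - 1, j + 1] + sm[kind[i - 1, j + 1], kind[i, j]]
            if (cand < best) { best <- cand; bi <- i - 1L; bj <- j + 1L }
          }
          if (is.finite(g_min[i - 1, j + 1])) {
            cand <- g_min[i - 1, j + 1] + lp * (i - j) - 2 * lp
            if (cand < best) {
              best <- cand
              bi <- g_arg_i[i - 1, j + 1]; bj <- g_arg_j[i - 1, j + 1]
            }
          }
        }
        dp[i, j] <- best; ptr_i[i, j] <- bi; ptr_j[i, j] <- bj
      }
      # update corner minimum at (i, j)
      gv <- if (is.finite(dp[i, j])) dp[i, j] - lp * i + lp * j else Inf
      gi <- i; gj <- j
      if (i > 1 && g_min[i - 1, j] < gv) {
        gv <- g_min[i - 1, j]; gi <- g_arg_i[i - 1, j]; gj <- g_arg_j[i - 1, j]
      }
      if (j < m && g_min[i, j + 1] < gv) {
        gv <- g_min[i, j + 1]; gi <- g_arg_i[i, j + 1]; gj <- g_arg_j[i, j + 1]
      }
      g_min[i, j] <- gv; g_arg_i[i, j] <- gi; g_arg_j[i, j] <- gj
    }
  }

  if (all(!is.finite(dp))) {
    return(list(mfe = 0, pairing = matrix(integer(0), 0, 2,
                                          dimnames = list(NULL, c("i", "j"))),
                n_pairs = 0L))
  }
  best_idx <- arrayInd(which.min(dp), dim(dp))
  total <- table$init + dp[best_idx[1], best_idx[2]]
  if (total >= 0) {
    return(list(mfe = 0, pairing = matrix(integer(0), 0, 2,
                                          dimnames = list(NULL, c("i", "j"))),
                n_pairs = 0L))
  }
  pairs <- list()
  ci <- best_idx[1]; cj <- best_idx[2]
  while (ci != 0L) {
    pairs[[length(pairs) + 1]] <- c(ci, cj)
    ni <- ptr_i[ci, cj]; nj <- ptr_j[ci, cj]
    ci <- ni; cj <- nj
  }
  pairing <- do.call(rbind, rev(pairs))
  colnames(pairing) <- c("i", "j")
  list(mfe = total, pairing = pairing, n_pairs = nrow(pairing))
}

#' Intramolecular fold minimum free energy
#'
#' Exact optimum over nested secondary structures (no pseudoknots) with
#' Watson-Crick/GU pairs, a minimum hairpin loop of 3 unpaired nt, and energy
#' equal to the sum of stack terms over stacked adjacent pairs; isolated pairs
#' contribute 0 and there are no initiation or loop terms, so the result is
#' always <= 0 (the empty structure is admissible). Sequences longer than
#' `max_len` are truncated to their first `max_len` nt.
#'
#' @param s RNA sequence (character; T is read as U).
#' @param table A `snohost_scoring` table.
#' @param max_len Truncation length in nt (default 1000).
#' @return MFE in kcal/mol (<= 0).
#' @examples
#' fold_mfe("GGGAAACCC")   # two GC/GC stacks: -6
#' @export
fold_mfe <- function(s, table = scoring_table(), max_len = 1000L) {
  s <- clean_rna(s, "s")
  if (nchar(s) > max_len) s <- substr(s, 1, max_len)
  codes <- base_codes(s)
  fold_mfe_cpp(codes, stack_matrix(table), 3L)
}

#' Normalise an energy per nucleotide
#'
#' @param energy Energy in kcal/mol.
#' @param length Sequence length in nt (post-truncation), >= 1.
#' @return `energy / length` in kcal/mol/nt.
#' @export
mfe_per_nt <- function(energy, length) {
  if (any(length < 1)) stop("length must be >= 1")
  energy / length
}

# ---- exhaustive-enumeration oracles (test ground truth, <= 14 nt total) ----

# standalone duplex scorer, independent of the DP: init + stacks + loop terms
score_duplex_pairing <- function(pairs, kinds, table) {
  if (nrow(pairs) == 0) return(0)
  e <- table$init
  if (nrow(pairs) > 1) {
    for (k in 2:nrow(pairs)) {
      di <- pairs[k, 1] - pairs[k - 1, 1]
      dj <- pairs[k - 1, 2] - pairs[k, 2]
      if (di == 1 && dj == 1) {
        e <- e + stack_matrix(table)[kinds[k - 1], kinds[k]]
      } else {
        e <- e + table$loop_penalty * ((di - 1) + (dj - 1))
      }
    }
  }
  e
}

enumerate_duplex <- function(a, b, table) {
  ca <- base_codes(clean_rna(a)); cb <- base_codes(clean_rna(b))
  n <- length(ca); m <- length(cb)
  kind <- outer(ca, cb, pair_kind_code)
  best <- 0
  rec <- function(min_i, max_j, pairs, kinds) {
    e <- score_duplex_pairing(pairs, kinds, table)
    if (e < best) best <<- e
    if (min_i > n || max_j < 1) return(invisible())
    for (i in min_i:n) {
      for (j in seq_len(max_j)) {
        if (!is.na(kind[i, j])) {
          rec(i + 1L, j - 1L,
              rbind(pairs, c(i, j)), c(kinds, kind[i, j]))
        }
      }
    }
    invisible()
  }
  rec(1L, m, matrix(integer(0), 0, 2), integer(0))
  best
}

# standalone fold scorer: sum of stacks over pairs (p,q) with (p+1,q-1) paired
score_fold_structure <- function(pairs, kinds, table) {
  if (nrow(pairs) < 2) return(0)
  sm <- stack_matrix(table)
  e <- 0
  key <- paste(pairs[, 1], pairs[, 2])
  for (k in seq_len(nrow(pairs))) {
    inner <- match(paste(pairs[k, 1] + 1, pairs[k, 2] - 1), key)
    if (!is.na(inner)) e <- e + sm[kinds[k], kinds[inner]]
  }
  e
}

enumerate_fold <- function(s, table, min_hairpin = 3L) {
  codes <- base_codes(clean_rna(s))
  n <- length(codes)
  # all nested structures on [i, j] as lists of pair matrices
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), 0, 2)))
    out <- enum(i + 1L, j)                       # i unpaired
    ks <- seq.int(i + min_hairpin + 1L, j)
    ks <- ks[ks <= j & ks >= i + min_hairpin + 1L]
    for (k in ks) {
      if (!is.na(pair_kind_code(codes[i], codes[k]))) {
        inner <- enum(i + 1L, k - 1L)
        outer_part <- enum(k + 1L, j)
        for (si in inner) for (so in outer_part) {
          out[[length(out) + 1]] <- rbind(c(i, k), si, so)
        }
      }
    }
    out
  }
  structures <- enum(1L, n)
  best <- 0
  for (st in structures) {
    kinds <- pair_kind_code(codes[st[, 1]], codes[st[, 2]])
    e <- score_fold_structure(st, kinds, table)
    if (e < best) best <- e
  }
  best
}

#' Exhaustive-enumeration energy oracle
#'
#' Computes the true optimum of the reduced energy model by enumerating every
#' valid co-linear duplex pairing (when `b` is given) or every valid nested
#' structure (when only `a` is given), scoring each with a standalone scorer.
#' Intended as an independent cross-check of [duplex_mfe()] / [fold_mfe()] on
#' small instances.
#'
#' @param a RNA sequence.
#' @param b Optional second RNA sequence (duplex mode).
#' @param table A `snohost_scoring` table.
#' @return Optimal energy in kcal/mol (<= 0).
#' @export
enumerate_oracle <- function(a, b = NULL, table = scoring_table()) {
  total <- nchar(a) + if (is.null(b)) 0 else nchar(b)
  if (total > 14) stop("enumeration oracle is limited to 14 nt total")
  if (is.null(b)) {
    min(0, enumerate_fold(a, table))
  } else {
    min(0, enumerate_duplex(a, b, table))
  }
}
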