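#' @title Sequence-level folding and domain-design matching
#' @name folding_match
#' @description A pluggable minimum-free-energy folding oracle over
#'   sequenced strand multisets, a well-formedness check mapping nucleotide
#'   pairings back to the domain-level design, and overlap matching against
#'   enumerated CRN structures.
NULL

#' Folding parameters
#'
#' @param max_complex_size maximum strands per folded complex (3 during
#'   optimization, 8 at re-evaluation).
#' @param hybridization_fraction minimum fraction of a domain's nucleotides
#'   that must be paired for the domain to count as hybridized.
#' @return a `fold_params` object.
#' @export
fold_params <- function(max_complex_size = 3L, hybridization_fraction = 0.5) {
  stopifnot(max_complex_size >= 1,
            hybridization_fraction > 0, hybridization_fraction <= 1)
  structure(list(max_complex_size = as.integer(max_complex_size),
                 hybridization_fraction = hybridization_fraction),
            class = "fold_params")
}

#' Sequence assignment for a library's base domains
#'
#' @param seqs named character vector: base domain name -> nucleotide string
#'   over A/C/G/T.
#' @param domain_lengths named integer vector of declared lengths (checked).
#' @return a `seq_assignment`; complement-domain sequences are derived as
#'   reverse complements on demand.
#' @export
seq_assignment <- function(seqs, domain_lengths) {
  stopifnot(setequal(names(seqs), names(domain_lengths)),
            all(nchar(seqs) == domain_lengths[names(seqs)]),
            all(grepl("^[ACGT]+$", seqs)))
  structure(list(seqs = seqs[names(domain_lengths)],
                 domain_lengths = domain_lengths),
            class = "seq_assignment")
}

#' Reverse complement of a DNA string
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Nucleotide sequence of a (possibly starred) domain token
#' @param dom domain tokens.
#' @param assignment a [seq_assignment()].
#' @return character vector of sequences (complements are reverse
#'   complements of the base sequence).
#' @export
domain_sequence <- function(dom, assignment) {
  base <- dom_base(dom)
  missing <- setdiff(unique(base), names(assignment$seqs))
  if (length(missing) > 0) {
    stop("no sequence assigned for domain(s): ",
         paste(missing, collapse = ", "))
  }
  s <- unname(assignment$seqs[base])
  ifelse(is_complement_token(dom), revcomp_dna(s), s)
}

# All orderings of a strand multiset that are distinct up to circular
# rotation (necklaces), in deterministic lexicographic order. `ids` is a
# character vector identifying the strands.
necklace_orderings <- function(ids) {
  n <- length(ids)
  if (n == 1) return(list(1L))
  perms <- all_permutations(n)
  seen <- character(0)
  out <- list()
  keys <- character(0)
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    # canonical rotation key on strand ids AND index order (so identical
    # strands in different slots do not collapse distinct pairings)
    strs <- vapply(0:(n - 1), function(k) {
      rot <- p[((seq_len(n) + k - 1) %% n) + 1]
      paste(ids[rot], collapse = " | ")
    }, character(1))
    key <- min(strs)
    if (key %in% keys) next
    keys <- c(keys, key)
    out[[length(out) + 1L]] <- p
  }
  out
}

# Maximum-weight non-crossing pairing over domain tokens (Nussinov-style
# dynamic program). tokens: character vector; weights: per-token length;
# can_pair: logical matrix. Returns list(score, pairs 2-col matrix).
nussinov_domains <- function(weights, can_pair) {
  n <- length(weights)
  W <- matrix(0, n, n)
  gv <- function(i, j) if (i > j) 0 else W[i, j]
  if (n >= 2) {
    for (span in 2:n) {
      for (i in 1:(n - span + 1)) {
        j <- i + span - 1
        best <- gv(i + 1, j)          # i unpaired (preferred on ties)
        for (k in (i + 1):j) {
          if (!can_pair[i, k]) next
          cand <- weights[i] + gv(i + 1, k - 1) + gv(k + 1, j)
          if (cand > best) best <- cand
        }
        W[i, j] <- best
      }
    }
  }
  # enumerate co-optimal pairings (bounded) so callers can prefer a
  # connected structure among score ties
  cap <- 64L
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    out <- list()
    if (gv(i, j) == gv(i + 1, j)) {
      out <- enum(i + 1, j)
    }
    for (k in (i + 1):j) {
      if (length(out) >= cap) break
      if (!can_pair[i, k]) next
      if (gv(i, j) != weights[i] + gv(i + 1, k - 1) + gv(k + 1, j)) next
      for (left in enum(i + 1, k - 1)) {
        for (right in enum(k + 1, j)) {
          if (length(out) >= cap) break
          out[[length(out) + 1L]] <- rbind(c(i, k), left, right)
        }
      }
    }
    if (length(out) > cap) out <- out[seq_len(cap)]
    out
  }
  pairings <- if (n >= 2) enum(1, n) else list(matrix(integer(0), ncol = 2))
  list(score = if (n >= 2) gv(1, n) else 0, pairings = pairings)
}

pairing_n_components <- function(n_strands, strand_of, pairs) {
  parent <- seq_len(n_strands)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(NROW(pairs))) {
    a <- find(strand_of[pairs[r, 1]]); b <- find(strand_of[pairs[r, 2]])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n_strands), find, integer(1))))
}

#' Fold a sequenced strand multiset (bundled MFE stand-in)
#'
#' Oracle contract: return one non-crossing pairing for the multiset. The
#' bundled deterministic stand-in maximizes the total number of paired
#' nucleotides over aligned pairings of fully sequence-complementary
#' domains: a dynamic program over domain tokens (with strand breaks),
#' maximized over strand orderings distinct up to rotation, with
#' lexicographic tie-breaks. Watson-Crick complementarity only (no G.T
#' wobble). External thermodynamic engines can be plugged in behind the
#' same contract via `engine`.
#'
#' @param strands list of strands (character vectors of domain tokens).
#' @param assignment a [seq_assignment()].
#' @param params a [fold_params()].
#' @param engine optional function(strands, assignment, params) returning a
#'   `folded_complex`, replacing the stand-in.
#' @return a `folded_complex`: fields `strands` (ordered as folded), `pairs`
#'   (domain-occurrence global-index pairs), `nt_pairs` (nucleotide-index
#'   pairs) and `score` (paired nucleotides).
#' @export
fold_mfe <- function(strands, assignment, params = fold_params(),
                     engine = NULL) {
  stopifnot(length(strands) >= 1,
            length(strands) <= params$max_complex_size)
  if (!is.null(engine)) return(engine(strands, assignment, params))
  ids <- vapply(strands, paste, character(1), collapse = " ")
  ord0 <- order(ids, method = "radix")
  strands <- strands[ord0]
  ids <- ids[ord0]
  doms <- unlist(strands)
  seqs <- domain_sequence(doms, assignment)   # errors on missing sequence
  best <- NULL
  for (p in necklace_orderings(ids)) {
    toks <- unlist(strands[p])
    tseq <- domain_sequence(toks, assignment)
    w <- nchar(tseq)
    n <- length(toks)
    can <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) can[i, j] <- tseq[j] == revcomp_dna(tseq[i])
      }
    }
    fit <- nussinov_domains(w, can)
    key <- paste(ids[p], collapse = " | ")
    # among co-optimal pairings prefer connected, then the lexicographically
    # smallest sorted pair list (deterministic tie-break)
    strand_of <- rep(seq_along(p), lengths(strands[p]))
    pick <- NULL
    for (pp in fit$pairings) {
      if (NROW(pp) > 1) pp <- pp[order(pp[, 1], pp[, 2]), , drop = FALSE]
      conn <- pairing_n_components(length(p), strand_of, pp) == 1L
      pkey <- paste(t(pp), collapse = ",")
      cand_p <- list(pairs = pp, connected = conn, pkey = pkey)
      if (is.null(pick) ||
          (conn && !pick$connected) ||
          (conn == pick$connected && pkey < pick$pkey)) {
        pick <- cand_p
      }
    }
    cand <- list(order = p, score = fit$score, pairs = pick$pairs,
                 connected = pick$connected, key = key, pkey = pick$pkey)
    better <- is.null(best) || cand$score > best$score ||
      (cand$score == best$score && cand$connected && !best$connected) ||
      (cand$score == best$score && cand$connected == best$connected &&
         cand$key < best$key)
    if (better) best <- cand
  }
  fstrands <- strands[best$order]
  lens <- lengths(fstrands)
  starts_nt <- cumsum(c(0L, nchar(domain_sequence(unlist(fstrands),
                                                  assignment))))
  nt_pairs <- matrix(integer(0), ncol = 2)
  if (nrow(best$pairs) > 0) {
    for (r in seq_len(nrow(best$pairs))) {
      i <- best$pairs[r, 1]; j <- best$pairs[r, 2]
      L <- nchar(domain_sequence(unlist(fstrands), assignment)[i])
      # aligned antiparallel: offset k of i pairs offset L-1-k of j
      nt_pairs <- rbind(nt_pairs,
                        cbind(starts_nt[i] + seq_len(L),
                              starts_nt[j] + L + 1L - seq_len(L)))
    }
  }
  structure(list(strands = fstrands, pairs = best$pairs,
                 nt_pairs = nt_pairs, score = best$score,
                 assignment = assignment),
            class = "folded_complex")
}

#' Well-formedness check: map a folded structure to the domain design
#'
#' Maps nucleotide pairings to domain occurrences. Rejects (returning
#' `ok = FALSE` and the offending nucleotide pair) if any paired nucleotide
#' joins non-complementary domain types or is mis-aligned (offset i of d
#' must pair offset len-1-i of d*). A domain-occurrence pair with at least
#' `hybridization_fraction` of its nucleotides paired becomes a domain-level
#' pair; the resulting domain-level complex must be non-crossing and
#' connected.
#'
#' @param folded a `folded_complex`.
#' @param params a [fold_params()].
#' @return list with `ok` (logical), `complex` (canonical `dsd_complex` when
#'   ok) or `reason`/`offending` on rejection.
#' @export
wellformed_domains <- function(folded, params = fold_params()) {
  strands <- folded$strands
  doms <- unlist(strands)
  dlens <- nchar(domain_sequence(doms, folded$assignment))
  occ_of_nt <- rep(seq_along(doms), dlens)
  starts_nt <- cumsum(c(0L, dlens))
  np <- folded$nt_pairs
  pair_counts <- list()
  if (NROW(np) > 0) {
    for (r in seq_len(nrow(np))) {
      a <- np[r, 1]; b <- np[r, 2]
      oa <- occ_of_nt[a]; ob <- occ_of_nt[b]
      if (doms[ob] != dom_complement(doms[oa])) {
        return(list(ok = FALSE, reason = "incompatible domains",
                    offending = c(a, b)))
      }
      offa <- a - starts_nt[oa] - 1L
      offb <- b - starts_nt[ob] - 1L
      if (offb != dlens[oa] - 1L - offa) {
        return(list(ok = FALSE, reason = "mis-aligned pairing",
                    offending = c(a, b)))
      }
      key <- paste(min(oa, ob), max(oa, ob))
      pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + 1L
    }
  }
  dom_pairs <- matrix(integer(0), ncol = 2)
  for (key in names(pair_counts)) {
    occs <- as.integer(strsplit(key, " ")[[1]])
    if (pair_counts[[key]] >=
        params$hybridization_fraction * dlens[occs[1]]) {
      dom_pairs <- rbind(dom_pairs, occs)
    }
  }
  comps <- components_of(strands, dom_pairs)
  if (is.null(comps)) {
    return(list(ok = FALSE, reason = "crossing domain-level pairing"))
  }
  if (length(comps) > 1) {
    return(list(ok = FALSE, reason = "disconnected complex"))
  }
  list(ok = TRUE, complex = comps[[1]])
}

# All multisets of `items` (indices) of sizes 1..max_size, as lists of
# index vectors (non-decreasing).
multisets_up_to <- function(n_items, max_size) {
  out <- list()
  grow <- function(prefix, start, left) {
    if (length(prefix) > 0) out[[length(out) + 1L]] <<- prefix
    if (left == 0) return(invisible(NULL))
    for (i in start:n_items) grow(c(prefix, i), i, left - 1L)
  }
  grow(integer(0), 1L, max_size)
  out
}

#' Fold all strand multisets and collect well-formed structures
#'
#' Emulates complex-ensemble enumeration: every multiset of the selected
#' strands up to `params$max_complex_size` is folded independently; folds
#' that pass [wellformed_domains()] contribute their canonical domain-level
#' complex.
#'
#' @param strands list of strands (character vectors).
#' @param assignment a [seq_assignment()].
#' @param params a [fold_params()].
#' @return named list of canonical `dsd_complex` keyed by kernel string.
#' @export
wellformed_structures <- function(strands, assignment,
                                  params = fold_params()) {
  out <- list()
  for (ms in multisets_up_to(length(strands), params$max_complex_size)) {
    folded <- fold_mfe(strands[ms], assignment, params)
    wf <- wellformed_domains(folded, params)
    if (!wf$ok) next
    k <- canonical_kernel(wf$complex)
    if (is.null(out[[k]])) out[[k]] <- wf$complex
  }
  out[sort(names(out))]
}

#' Overlap between folded well-formed structures and an enumerated CRN
#'
#' Both sides are canonicalized (circular strand-order permutation checked
#' via [canonical_form()]); the denominator counts enumerated structures
#' with strand count at most `params$max_complex_size` (only those are
#' observable by the folding side).
#'
#' @param folded named list of well-formed `dsd_complex` (e.g. from
#'   [wellformed_structures()]).
#' @param crn a `dsd_crn` for the same strand set.
#' @param params a [fold_params()].
#' @return a `match_report`: `n_overlap`, `n_enumerated`, `proportion`
#'   (percent), `matched` (canonical kernel strings).
#' @export
match_overlap <- function(folded, crn, params = fold_params()) {
  enum_k <- names(crn$structures)
  sizes <- vapply(crn$structures, complex_size, integer(1))
  enum_k <- enum_k[sizes <= params$max_complex_size]
  fold_k <- vapply(folded, canonical_kernel, character(1))
  matched <- sort(intersect(unname(fold_k), enum_k))
  n_enum <- length(enum_k)
  structure(list(n_overlap = length(matched), n_enumerated = n_enum,
                 proportion = if (n_enum > 0) 100 * length(matched) / n_enum
                              else 0,
                 matched = matched,
                 hybridization_fraction = params$hybridization_fraction,
                 max_complex_size = params$max_complex_size),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d / %d overlap (%.3f%%), size cap %d\n",
              x$n_overlap, x$n_enumerated, x$proportion,
              x$max_complex_size))
  invisible(x)
}

#' Read / write sequence assignments as FASTA
#'
#' One record per base domain (record id = domain name). Requires the
#' Biostrings package.
#'
#' @param assignment a [seq_assignment()].
#' @param path file path.
#' @return `write_assignment_fasta` invisibly returns `path`;
#'   `read_assignment_fasta` returns a `seq_assignment`.
#' @export
write_assignment_fasta <- function(assignment, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA I/O")
  }
  x <- Biostrings::DNAStringSet(assignment$seqs)
  names(x) <- names(assignment$seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_assignment_fasta
#' @param domain_lengths named integer vector of declared lengths.
#' @export
read_assignment_fasta <- function(path, domain_lengths) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA I/O")
  }
  x <- Biostrings::readDNAStringSet(path)
  seq_assignment(stats::setNames(as.character(x), names(x)), domain_lengths)
}
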