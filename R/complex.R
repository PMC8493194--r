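#' @title Domain-level model of multistranded DNA complexes
#' @description Internal representation: a complex is a circularly ordered
#'   list of strands (each a character vector of domain tokens such as
#'   `"a"` or `"a*"`) plus a pairing vector over the global occurrence
#'   indices obtained by concatenating the strands in order. `pairing[i] = j`
#'   means occurrence i is paired with occurrence j (and vice versa); NA
#'   marks an unpaired domain. Pairings must be complementary, non-crossing
#'   with respect to the stored strand order, and (for multistranded
#'   complexes) connect all strands.
#' @name complex-model
NULL

#' Complement of a domain token
#'
#' Appends or strips the trailing `*` marker; `x**` is normalized to `x`.
#'
#' @param dom character vector of domain tokens.
#' @return character vector of complementary tokens.
#' @examples
#' dom_complement(c("a", "b*"))  # "a*" "b"
#' @export
dom_complement <- function(dom) {
  ifelse(is_complement_token(dom), dom_base(dom), paste0(dom_base(dom), "*"))
}

#' @rdname dom_complement
#' @export
is_complement_token <- function(dom) {
  n <- nchar(sub("\\*+$", "", dom))
  stars <- nchar(dom) - n
  stars %% 2L == 1L
}

#' Base (unstarred) name of a domain token
#' @param dom character vector of domain tokens.
#' @return character vector of base names.
#' @export
dom_base <- function(dom) sub("\\*+$", "", dom)

#' Normalize a domain token (collapse repeated `*`)
#' @param dom character vector of tokens.
#' @return normalized tokens where an even number of stars cancels out.
#' @export
dom_normalize <- function(dom) {
  ifelse(is_complement_token(dom), paste0(dom_base(dom), "*"), dom_base(dom))
}

#' Nucleotide length of domain tokens
#'
#' @param dom character vector of (possibly starred) domain tokens.
#' @param domains named integer vector mapping base domain names to lengths.
#' @return integer vector of lengths.
#' @export
dom_length <- function(dom, domains) {
  base <- dom_base(dom)
  bad <- setdiff(unique(base), names(domains))
  if (length(bad) > 0) {
    stop("unknown domain(s): ", paste(bad, collapse = ", "))
  }
  unname(domains[base])
}

#' Construct a complex from strands and pairs
#'
#' @param strands list of character vectors of domain tokens (one per
#'   strand, 5' to 3').
#' @param pairs two-column integer matrix of paired global occurrence
#'   indices (order within a row irrelevant), or NULL for no pairs.
#' @param validate check complementarity, crossing and connectivity.
#' @return an object of class `dsd_complex`.
#' @export
new_complex <- function(strands, pairs = NULL, validate = TRUE) {
  strands <- lapply(strands, function(s) dom_normalize(as.character(s)))
  stopifnot(length(strands) >= 1, all(lengths(strands) >= 1))
  n_occ <- sum(lengths(strands))
  pairing <- rep(NA_integer_, n_occ)
  if (!is.null(pairs) && NROW(pairs) > 0) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (i == j || i < 1 || j > n_occ) stop("invalid pair indices")
      if (!is.na(pairing[i]) || !is.na(pairing[j])) {
        stop("occurrence paired twice")
      }
      pairing[i] <- j
      pairing[j] <- i
    }
  }
  cx <- structure(list(strands = strands, pairing = pairing),
                  class = "dsd_complex")
  if (validate) validate_complex(cx)
  cx
}

#' Global occurrence layout of a complex
#'
#' @param cx a `dsd_complex`.
#' @return data.frame with columns occ, strand, pos (0-based within strand),
#'   dom.
#' @export
complex_occurrences <- function(cx) {
  lens <- lengths(cx$strands)
  data.frame(
    occ = seq_len(sum(lens)),
    strand = rep(seq_along(cx$strands), lens),
    pos = unlist(lapply(lens, function(l) seq_len(l) - 1L)),
    dom = unlist(cx$strands),
    stringsAsFactors = FALSE
  )
}

#' Validate a complex
#'
#' Checks pair complementarity, the non-crossing (pseudoknot-free)
#' condition relative to the stored strand order, and connectivity of the
#' strand graph (single-strand complexes are trivially connected).
#'
#' @param cx a `dsd_complex`.
#' @return invisibly TRUE; stops on violation.
#' @export
validate_complex <- function(cx) {
  doms <- unlist(cx$strands)
  p <- cx$pairing
  idx <- which(!is.na(p))
  if (any(p[p[idx]] != idx)) stop("pairing vector not symmetric")
  if (length(idx) > 0) {
    if (any(doms[idx] != dom_complement(doms[p[idx]]))) {
      stop("pair joins non-complementary domains")
    }
  }
  if (has_crossing(cx)) stop("crossing pairs (pseudoknot)")
  if (!is_connected_complex(cx)) stop("complex is not connected")
  invisible(TRUE)
}

#' Pair list of a complex
#' @param cx a `dsd_complex`.
#' @return two-column matrix of global occurrence pairs with col1 < col2.
#' @export
complex_pairs <- function(cx) {
  i <- which(!is.na(cx$pairing))
  i <- i[i < cx$pairing[i]]
  cbind(i, cx$pairing[i], deparse.level = 0)
}

#' Test for crossing (pseudoknotted) pairs
#'
#' Independent O(p^2) test: pairs (i1, j1) and (i2, j2) (each sorted) cross
#' iff i1 < i2 < j1 < j2 in the linearized occurrence order.
#'
#' @param cx a `dsd_complex` (or a list with a `pairing` vector).
#' @return logical.
#' @export
has_crossing <- function(cx) {
  pr <- complex_pairs(cx)
  n <- nrow(pr)
  if (n < 2) return(FALSE)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      i1 <- pr[a, 1]; j1 <- pr[a, 2]; i2 <- pr[b, 1]; j2 <- pr[b, 2]
      if ((i1 < i2 && i2 < j1 && j1 < j2) ||
          (i2 < i1 && i1 < j2 && j2 < j1)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Connectivity of the strand graph under pairings
#' @param cx a `dsd_complex`.
#' @return logical; TRUE when every strand is reachable from every other via
#'   pairs (always TRUE for a single strand).
#' @export
is_connected_complex <- function(cx) {
  ns <- length(cx$strands)
  if (ns == 1) return(TRUE)
  occ <- complex_occurrences(cx)
  parent <- seq_len(ns)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  pr <- complex_pairs(cx)
  for (r in seq_len(nrow(pr))) {
    a <- find(occ$strand[pr[r, 1]]); b <- find(occ$strand[pr[r, 2]])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(ns), find, integer(1)))) == 1
}

#' Rotate the circular strand order of a complex
#'
#' @param cx a `dsd_complex`.
#' @param k number of positions to rotate (strand k+1 becomes first).
#' @return the rotated `dsd_complex` (pair indices remapped); the rotation
#'   is applied without validation so callers can test non-crossing.
#' @export
rotate_complex <- function(cx, k) {
  ns <- length(cx$strands)
  k <- ((k %% ns) + ns) %% ns
  if (k == 0) return(cx)
  ord <- c((k + 1):ns, 1:k)
  reorder_complex(cx, ord)
}

# Reorder strands by `ord` (a permutation); remaps the pairing vector.
reorder_complex <- function(cx, ord) {
  lens <- lengths(cx$strands)
  starts <- cumsum(c(0L, lens))[seq_along(lens)]
  new_lens <- lens[ord]
  new_starts <- cumsum(c(0L, new_lens))[seq_along(ord)]
  # map old global index -> new global index
  map <- integer(sum(lens))
  for (newpos in seq_along(ord)) {
    s <- ord[newpos]
    map[starts[s] + seq_len(lens[s])] <- new_starts[newpos] + seq_len(lens[s])
  }
  new_pairing <- rep(NA_integer_, sum(lens))
  old_idx <- which(!is.na(cx$pairing))
  new_pairing[map[old_idx]] <- map[cx$pairing[old_idx]]
  structure(list(strands = cx$strands[ord], pairing = new_pairing),
            class = "dsd_complex")
}

#' Canonical form of a complex
#'
#' Among all circular rotations of the strand order that keep the pairing
#' non-crossing, returns the rotation whose kernel string is
#' lexicographically minimal. Idempotent; two complexes are equal iff their
#' canonical kernel strings are equal.
#'
#' @param cx a `dsd_complex`.
#' @return the canonical `dsd_complex`, with the canonical kernel string in
#'   attribute `"kernel"`.
#' @export
canonical_form <- function(cx) {
  ns <- length(cx$strands)
  best <- NULL
  best_str <- NULL
  for (k in 0:(ns - 1)) {
    rot <- rotate_complex(cx, k)
    if (has_crossing(rot)) next
    s <- write_kernel(rot)
    if (is.null(best_str) || s < best_str) {
      best_str <- s
      best <- rot
    }
  }
  if (is.null(best)) stop("no non-crossing rotation found")
  attr(best, "kernel") <- best_str
  best
}

#' Canonical kernel string of a complex
#' @param cx a `dsd_complex`.
#' @return character scalar, the kernel string of [canonical_form()].
#' @export
canonical_kernel <- function(cx) {
  k <- attr(cx, "kernel")
  if (!is.null(k)) return(k)
  attr(canonical_form(cx), "kernel")
}

# Find a strand ordering making `pairs` (global indices relative to the
# given order) non-crossing. Tries the given order first, then all
# permutations (strand counts here are <= max_complex_size, i.e. small).
# Returns a valid dsd_complex or NULL.
find_noncrossing_order <- function(strands, global_pairs) {
  try_order <- function(ord) {
    lens <- lengths(strands)
    starts <- cumsum(c(0L, lens))[seq_along(lens)]
    new_starts <- cumsum(c(0L, lens[ord]))[seq_along(ord)]
    map <- integer(sum(lens))
    for (newpos in seq_along(ord)) {
      s <- ord[newpos]
      map[starts[s] + seq_len(lens[s])] <-
        new_starts[newpos] + seq_len(lens[s])
    }
    pr <- cbind(map[global_pairs[, 1]], map[global_pairs[, 2]])
    cx <- tryCatch(new_complex(strands[ord], pr, validate = FALSE),
                   error = function(e) NULL)
    if (is.null(cx) || has_crossing(cx)) return(NULL)
    cx
  }
  if (is.null(global_pairs)) global_pairs <- matrix(integer(0), ncol = 2)
  ns <- length(strands)
  cx <- try_order(seq_len(ns))
  if (!is.null(cx)) return(cx)
  if (ns > 7) return(NULL)  # permutation search bounded; caller discards
  perms <- all_permutations(ns)
  for (r in seq_len(nrow(perms))) {
    cx <- try_order(perms[r, ])
    if (!is.null(cx)) return(cx)
  }
  NULL
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (r in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1)[1:n]
      row <- row + 1L
    }
  }
  # standard: insert n in each position of each (n-1)-permutation
  out
}

#' Number of strands in a complex
#' @param cx a `dsd_complex`.
#' @return integer strand count.
#' @export
complex_size <- function(cx) length(cx$strands)

#' @export
print.dsd_complex <- function(x, ...) {
  cat("<dsd_complex> ", write_kernel(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.dsd_complex <- function(x, ...) write_kernel(x)
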