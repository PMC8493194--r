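#' @title Domain-level reaction move generators
#' @description The four Peppercorn-style move types: hybridization (bind),
#'   dissociation (open), three-way and four-way branch migration. Each
#'   generator returns a list of reactions; a reaction is a list with fields
#'   `rtype`, `reactants` and `products` (sorted canonical kernel strings).
#' @name moves
NULL

#' Enumeration parameters
#'
#' @param max_complex_size maximum strands per complex (default 6).
#' @param release_cutoff maximum nucleotide length of a duplex domain that
#'   may spontaneously open; NULL means "max domain length in the library"
#'   (resolved by [enumerate_crn()]).
#' @param max_structures,max_reactions hard caps; when one fires the CRN is
#'   returned with `truncated = TRUE`.
#' @param transient_policy when TRUE, resting/transient condensation is
#'   applied and only resting complexes take part in intermolecular binds.
#' @return an `enum_params` object.
#' @export
enum_params <- function(max_complex_size = 6L, release_cutoff = NULL,
                        max_structures = 5000L, max_reactions = 20000L,
                        transient_policy = TRUE) {
  stopifnot(max_complex_size >= 1, max_structures >= 1, max_reactions >= 1,
            is.null(release_cutoff) || release_cutoff >= 0)
  structure(list(max_complex_size = as.integer(max_complex_size),
                 release_cutoff = release_cutoff,
                 max_structures = as.integer(max_structures),
                 max_reactions = as.integer(max_reactions),
                 transient_policy = isTRUE(transient_policy)),
            class = "enum_params")
}

new_reaction <- function(rtype, reactant_kernels, product_kernels) {
  list(rtype = rtype,
       reactants = sort(reactant_kernels),
       products = sort(product_kernels))
}

reaction_key <- function(r) {
  paste(r$rtype, paste(r$reactants, collapse = " | "), "->",
        paste(r$products, collapse = " | "))
}

is_noop_reaction <- function(r) {
  identical(r$reactants, r$products)
}

# Split a complex into connected components after a pairing rewrite.
# `strands` is the strand list, `pairs` a 2-col matrix of global indices.
# Returns a list of canonical dsd_complex (one per component) or NULL when
# some component admits no non-crossing strand order.
components_of <- function(strands, pairs) {
  ns <- length(strands)
  lens <- lengths(strands)
  starts <- cumsum(c(0L, lens))[seq_len(ns)]
  strand_of <- rep(seq_len(ns), lens)
  parent <- seq_len(ns)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (NROW(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(strand_of[pairs[r, 1]]); b <- find(strand_of[pairs[r, 2]])
      if (a != b) parent[a] <- b
    }
  }
  comp <- vapply(seq_len(ns), find, integer(1))
  out <- list()
  for (cid in unique(comp)) {
    sel <- which(comp == cid)           # induced order preserved
    sub_strands <- strands[sel]
    sub_lens <- lens[sel]
    sub_starts <- cumsum(c(0L, sub_lens))[seq_along(sel)]
    gmap <- rep(NA_integer_, sum(lens))
    for (t in seq_along(sel)) {
      s <- sel[t]
      gmap[starts[s] + seq_len(lens[s])] <- sub_starts[t] + seq_len(lens[s])
    }
    sub_pairs <- NULL
    if (NROW(pairs) > 0) {
      keep <- strand_of[pairs[, 1]] %in% sel
      if (any(keep)) {
        sub_pairs <- cbind(gmap[pairs[keep, 1]], gmap[pairs[keep, 2]])
      }
    }
    cx <- find_noncrossing_order(sub_strands, sub_pairs)
    if (is.null(cx)) return(NULL)
    out[[length(out) + 1L]] <- canonical_form(cx)
  }
  out
}

#' Hybridization (bind) moves
#'
#' Intramolecular when `b` is NULL: one reaction per admissible new pair
#' between an unpaired domain and an unpaired complement within `a`.
#' Intermolecular otherwise: pairs across `a` and `b`; the product joins the
#' two complexes (connected by construction) and must admit a non-crossing
#' strand order.
#'
#' @param a,b `dsd_complex` objects (`b = NULL` for intramolecular moves).
#' @param params an [enum_params()].
#' @return list of reactions (possibly empty).
#' @export
bind_moves <- function(a, b = NULL, params = enum_params()) {
  out <- list()
  seen <- character(0)
  if (is.null(b)) {
    occ <- complex_occurrences(a)
    free <- which(is.na(a$pairing))
    ra <- canonical_kernel(a)
    if (length(free) >= 2) {
      for (ii in seq_along(free)) {
        for (jj in seq_along(free)) {
          if (jj <= ii) next
          i <- free[ii]; j <- free[jj]
          if (occ$dom[j] != dom_complement(occ$dom[i])) next
          pairs <- rbind(complex_pairs(a), c(i, j))
          comps <- components_of(a$strands, pairs)
          if (is.null(comps)) next
          r <- new_reaction("bind", ra,
                            vapply(comps, canonical_kernel, character(1)))
          if (is_noop_reaction(r)) next
          k <- reaction_key(r)
          if (!(k %in% seen)) {
            seen <- c(seen, k)
            out[[length(out) + 1L]] <- r
          }
        }
      }
    }
    return(out)
  }
  if (complex_size(a) + complex_size(b) > params$max_complex_size) {
    return(out)
  }
  occ_a <- complex_occurrences(a)
  occ_b <- complex_occurrences(b)
  off <- nrow(occ_a)
  strands <- c(a$strands, b$strands)
  base_pairs <- rbind(complex_pairs(a), complex_pairs(b) + off)
  free_a <- which(is.na(a$pairing))
  free_b <- which(is.na(b$pairing))
  rks <- sort(c(canonical_kernel(a), canonical_kernel(b)))
  for (i in free_a) {
    for (j in free_b) {
      if (occ_b$dom[j] != dom_complement(occ_a$dom[i])) next
      pairs <- rbind(base_pairs, c(i, j + off))
      comps <- components_of(strands, pairs)
      if (is.null(comps)) next
      r <- new_reaction("bind", rks,
                        vapply(comps, canonical_kernel, character(1)))
      if (is_noop_reaction(r)) next
      k <- reaction_key(r)
      if (!(k %in% seen)) {
        seen <- c(seen, k)
        out[[length(out) + 1L]] <- r
      }
    }
  }
  out
}

#' Dissociation (open) moves
#'
#' One reaction per existing pair whose domain length is at most
#' `release_cutoff`; removing the pair leaves either one connected product
#' or two products (split into canonical components).
#'
#' @param cx a `dsd_complex`.
#' @param domains named integer vector of base-domain lengths.
#' @param params an [enum_params()] with a resolved (non-NULL)
#'   `release_cutoff`.
#' @return list of reactions.
#' @export
open_moves <- function(cx, domains, params = enum_params(release_cutoff = Inf)) {
  out <- list()
  seen <- character(0)
  cutoff <- params$release_cutoff
  if (is.null(cutoff)) stop("release_cutoff must be resolved")
  occ <- complex_occurrences(cx)
  pr <- complex_pairs(cx)
  rk <- canonical_kernel(cx)
  for (r in seq_len(nrow(pr))) {
    if (dom_length(occ$dom[pr[r, 1]], domains) > cutoff) next
    pairs <- pr[-r, , drop = FALSE]
    comps <- components_of(cx$strands, pairs)
    if (is.null(comps)) next
    rx <- new_reaction("open", rk,
                       vapply(comps, canonical_kernel, character(1)))
    if (is_noop_reaction(rx)) next
    k <- reaction_key(rx)
    if (!(k %in% seen)) {
      seen <- c(seen, k)
      out[[length(out) + 1L]] <- rx
    }
  }
  out
}

# Shared plumbing for the two branch-migration generators: apply a pair
# rewrite (drop rows `drop`, add rows `add`) and package the reaction.
rewrite_reaction <- function(cx, drop, add, rtype) {
  pr <- complex_pairs(cx)
  keep <- rep(TRUE, nrow(pr))
  for (d in seq_len(NROW(drop))) {
    hit <- which(pr[, 1] == min(drop[d, ]) & pr[, 2] == max(drop[d, ]))
    keep[hit] <- FALSE
  }
  pairs <- rbind(pr[keep, , drop = FALSE],
                 t(apply(matrix(add, ncol = 2), 1, sort)))
  comps <- components_of(cx$strands, pairs)
  if (is.null(comps)) return(NULL)
  r <- new_reaction(rtype, canonical_kernel(cx),
                    vapply(comps, canonical_kernel, character(1)))
  if (is_noop_reaction(r)) return(NULL)
  r
}

#' Three-way branch migration moves
#'
#' An unpaired invader domain `x`, immediately adjacent along its strand to
#' an anchor pair (w, w*), displaces the incumbent occurrence currently
#' paired to the complement `x*` that sits adjacent to w* (continuing the
#' helix). Remote (non-adjacent) toeholds are deliberately excluded.
#'
#' @param cx a `dsd_complex`.
#' @param params an [enum_params()].
#' @return list of reactions.
#' @export
branch3_moves <- function(cx, params = enum_params()) {
  out <- list()
  seen <- character(0)
  occ <- complex_occurrences(cx)
  p <- cx$pairing
  lens <- lengths(cx$strands)
  for (gx in which(is.na(p))) {
    s <- occ$strand[gx]; pos <- occ$pos[gx]
    for (dir in c(-1L, 1L)) {
      # anchor w sits at pos - dir... no: w is the neighbour in direction -dir
      wpos <- pos - dir
      if (wpos < 0 || wpos >= lens[s]) next
      gw <- gx - dir                      # same strand, adjacent occurrence
      if (is.na(p[gw])) next              # anchor must be paired
      gw2 <- p[gw]                        # w* location
      s2 <- occ$strand[gw2]; p2 <- occ$pos[gw2]
      # helix continuation on the w* strand runs antiparallel
      tpos <- p2 - dir
      if (tpos < 0 || tpos >= lens[s2]) next
      gt <- gw2 - dir
      if (occ$strand[gt] != s2) next
      if (occ$dom[gt] != dom_complement(occ$dom[gx])) next
      if (is.na(p[gt])) next
      gold <- p[gt]
      if (gold == gx) next
      r <- rewrite_reaction(cx, drop = matrix(c(gt, gold), ncol = 2),
                            add = c(min(gt, gx), max(gt, gx)),
                            rtype = "branch3")
      if (is.null(r)) next
      k <- reaction_key(r)
      if (!(k %in% seen)) {
        seen <- c(seen, k)
        out[[length(out) + 1L]] <- r
      }
    }
  }
  out
}

#' Four-way branch migration moves
#'
#' Two helices of the same domain type meeting at a junction exchange
#' partners: pairs (p, p*1) and (q, q*2) with dom(p) = dom(q) rewrite to
#' (p, q*2) and (q, p*1). The junction condition requires an endpoint of one
#' pair to be immediately strand-adjacent to an endpoint of the other.
#' Crossing or no-op results are discarded.
#'
#' @param cx a `dsd_complex`.
#' @param params an [enum_params()].
#' @return list of reactions.
#' @export
branch4_moves <- function(cx, params = enum_params()) {
  out <- list()
  seen <- character(0)
  occ <- complex_occurrences(cx)
  pr <- complex_pairs(cx)
  n <- nrow(pr)
  if (n < 2) return(out)
  adjacent <- function(i, j) {
    occ$strand[i] == occ$strand[j] && abs(occ$pos[i] - occ$pos[j]) == 1L
  }
  offset1 <- function(i, j) {
    # +1/-1 when j is the next/previous occurrence on i's strand, else NA
    if (occ$strand[i] != occ$strand[j]) return(NA_integer_)
    d <- occ$pos[j] - occ$pos[i]
    if (abs(d) == 1L) d else NA_integer_
  }
  stacked <- function(e1, e2) {
    # consecutive rungs of one helix: endpoints advance by +1 on one strand
    # and -1 on the partner strand (antiparallel continuation)
    for (sw in list(e2, rev(e2))) {
      d1 <- offset1(e1[1], sw[1]); d2 <- offset1(e1[2], sw[2])
      if (!is.na(d1) && !is.na(d2) && d1 == -d2) return(TRUE)
    }
    FALSE
  }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      e1 <- pr[a, ]; e2 <- pr[b, ]
      # orient so A and C carry the same (base or starred) domain token
      if (occ$dom[e1[1]] == occ$dom[e2[1]]) {
        A <- e1[1]; B <- e1[2]; C <- e2[1]; D <- e2[2]
      } else if (occ$dom[e1[1]] == occ$dom[e2[2]]) {
        A <- e1[1]; B <- e1[2]; C <- e2[2]; D <- e2[1]
      } else {
        next
      }
      junction <- adjacent(A, C) || adjacent(A, D) ||
        adjacent(B, C) || adjacent(B, D)
      if (!junction) next
      if (stacked(e1, e2)) next
      r <- rewrite_reaction(cx, drop = rbind(e1, e2),
                            add = rbind(c(A, D), c(C, B)),
                            rtype = "branch4")
      if (is.null(r)) next
      k <- reaction_key(r)
      if (!(k %in% seen)) {
        seen <- c(seen, k)
        out[[length(out) + 1L]] <- r
      }
    }
  }
  out
}
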