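# Shared fixtures and independent brute-force oracles.

toy_spec <- function() library_spec(2, c(a = 10L), "toy21")
toy_library <- function() build_library(toy_spec())
toy_domains <- function() c(a = 10L)

fig1_params <- function(max_complex_size = 2L) {
  enum_params(max_complex_size = max_complex_size, release_cutoff = 10)
}

reaction_strings <- function(crn) {
  sort(vapply(crn$reactions, function(r) {
    sprintf("[%s] %s -> %s", r$rtype,
            paste(r$reactants, collapse = " + "),
            paste(r$products, collapse = " + "))
  }, character(1)))
}

# ---- independent crossing test -------------------------------------------
# O(p^2) quadruple check over sorted pair intervals, written against the
# raw pair matrix rather than the complex accessors.
oracle_crossing <- function(pairs) {
  if (NROW(pairs) < 2) return(FALSE)
  iv <- t(apply(pairs, 1, range))
  for (a in seq_len(nrow(iv))) {
    for (b in seq_len(nrow(iv))) {
      if (a == b) next
      if (iv[a, 1] < iv[b, 1] && iv[b, 1] < iv[a, 2] &&
          iv[a, 2] < iv[b, 2]) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# ---- independent complex validity ----------------------------------------
# strands: list of token vectors; pairs: 2-col global indices under the
# given strand order. Valid iff connected and SOME strand permutation makes
# the pairing non-crossing. Returns the canonical kernel or NULL.
oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

oracle_canonical <- function(strands, pairs) {
  ns <- length(strands)
  lens <- lengths(strands)
  strand_of <- rep(seq_len(ns), lens)
  # connectivity by BFS over the strand graph
  if (ns > 1) {
    nbr <- lapply(seq_len(ns), function(i) integer(0))
    for (r in seq_len(NROW(pairs))) {
      u <- strand_of[pairs[r, 1]]; v <- strand_of[pairs[r, 2]]
      nbr[[u]] <- c(nbr[[u]], v); nbr[[v]] <- c(nbr[[v]], u)
    }
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier) > 0) {
      nxt <- setdiff(unlist(nbr[frontier]), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) < ns) return(NULL)
  }
  starts <- cumsum(c(0L, lens))[seq_len(ns)]
  best <- NULL
  for (perm in oracle_permutations(ns)) {
    new_starts <- cumsum(c(0L, lens[perm]))[seq_len(ns)]
    map <- integer(sum(lens))
    for (t in seq_len(ns)) {
      s <- perm[t]
      map[starts[s] + seq_len(lens[s])] <- new_starts[t] + seq_len(lens[s])
    }
    pp <- if (NROW(pairs) > 0) {
      cbind(map[pairs[, 1]], map[pairs[, 2]])
    } else {
      matrix(integer(0), ncol = 2)
    }
    if (oracle_crossing(pp)) next
    cx <- new_complex(strands[perm], pp, validate = FALSE)
    k <- write_kernel(cx)
    if (is.null(best) || k < best) best <- k
  }
  if (is.null(best)) return(NULL)
  # reduce to the rotation-canonical representative used by the package
  canonical_kernel(parse_kernel(best))
}

# ---- exhaustive rewrite oracles for the move generators ------------------
# All single pair additions / removals / exchanges, with independent
# validity filters; locality conditions for the branch migrations are
# re-encoded set-theoretically (see the decisions notes).
oracle_products <- function(strands, pairs) {
  ns <- length(strands)
  lens <- lengths(strands)
  strand_of <- rep(seq_len(ns), lens)
  # connected components of strands
  comp <- seq_len(ns)
  repeat {
    changed <- FALSE
    for (r in seq_len(NROW(pairs))) {
      u <- strand_of[pairs[r, 1]]; v <- strand_of[pairs[r, 2]]
      m <- min(comp[u], comp[v])
      if (comp[u] != m || comp[v] != m) {
        comp[comp == comp[u] | comp == comp[v]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- character(0)
  starts <- cumsum(c(0L, lens))[seq_len(ns)]
  for (cid in unique(comp)) {
    sel <- which(comp == cid)
    sub <- strands[sel]
    map <- rep(NA_integer_, sum(lens))
    ns2 <- cumsum(c(0L, lens[sel]))
    for (t in seq_along(sel)) {
      s <- sel[t]
      map[starts[s] + seq_len(lens[s])] <- ns2[t] + seq_len(lens[s])
    }
    keep <- NROW(pairs) > 0 & strand_of[pairs[, 1]] %in% sel
    pp <- if (any(keep)) cbind(map[pairs[keep, 1]], map[pairs[keep, 2]])
          else matrix(integer(0), ncol = 2)
    k <- oracle_canonical(sub, pp)
    if (is.null(k)) return(NULL)
    out <- c(out, k)
  }
  sort(out)
}

oracle_reaction_set <- function(rtype, reactants, products_list) {
  unlist(lapply(products_list, function(p) {
    if (identical(sort(reactants), p)) return(NULL)   # no-op suppressed
    sprintf("[%s] %s -> %s", rtype, paste(sort(reactants), collapse = " + "),
            paste(p, collapse = " + "))
  }))
}

oracle_bind_intra <- function(cx) {
  occ <- complex_occurrences(cx)
  free <- which(is.na(cx$pairing))
  res <- character(0)
  for (i in free) {
    for (j in free) {
      if (j <= i) next
      if (occ$dom[j] != dom_complement(occ$dom[i])) next
      p <- oracle_products(cx$strands, rbind(complex_pairs(cx), c(i, j)))
      if (is.null(p)) next
      res <- c(res, oracle_reaction_set("bind", canonical_kernel(cx),
                                        list(p)))
    }
  }
  sort(unique(res))
}

oracle_bind_inter <- function(a, b, max_size = 3L) {
  if (complex_size(a) + complex_size(b) > max_size) return(character(0))
  occa <- complex_occurrences(a); occb <- complex_occurrences(b)
  off <- nrow(occa)
  strands <- c(a$strands, b$strands)
  base <- rbind(complex_pairs(a), complex_pairs(b) + off)
  res <- character(0)
  reac <- c(canonical_kernel(a), canonical_kernel(b))
  for (i in which(is.na(a$pairing))) {
    for (j in which(is.na(b$pairing))) {
      if (occb$dom[j] != dom_complement(occa$dom[i])) next
      p <- oracle_products(strands, rbind(base, c(i, j + off)))
      if (is.null(p)) next
      res <- c(res, oracle_reaction_set("bind", reac, list(p)))
    }
  }
  sort(unique(res))
}

oracle_open <- function(cx, domains, cutoff) {
  occ <- complex_occurrences(cx)
  pr <- complex_pairs(cx)
  res <- character(0)
  for (r in seq_len(NROW(pr))) {
    if (dom_length(occ$dom[pr[r, 1]], domains) > cutoff) next
    p <- oracle_products(cx$strands, pr[-r, , drop = FALSE])
    if (is.null(p)) next
    res <- c(res, oracle_reaction_set("open", canonical_kernel(cx), list(p)))
  }
  sort(unique(res))
}

oracle_branch3 <- function(cx) {
  occ <- complex_occurrences(cx)
  pr <- complex_pairs(cx)
  pairing <- cx$pairing
  res <- character(0)
  adjacent_offset <- function(i, j) {
    if (occ$strand[i] != occ$strand[j]) return(NA_integer_)
    d <- occ$pos[j] - occ$pos[i]
    if (abs(d) == 1L) d else NA_integer_
  }
  for (x in which(is.na(pairing))) {
    for (r in seq_len(NROW(pr))) {          # (u, v): x replaces u, pairs v
      for (ori in 1:2) {
        u <- pr[r, ori]; v <- pr[r, 3 - ori]
        if (occ$dom[x] != occ$dom[u]) next
        # locality: anchor pair (w, w*) with w next to x, v next to w* on
        # the opposite helix side
        ok <- FALSE
        for (rr in seq_len(NROW(pr))) {
          if (rr == r) next
          for (o2 in 1:2) {
            w <- pr[rr, o2]; wstar <- pr[rr, 3 - o2]
            d <- adjacent_offset(w, x)
            if (is.na(d)) next
            d2 <- adjacent_offset(wstar, v)
            if (!is.na(d2) && d2 == -d) ok <- TRUE
          }
        }
        if (!ok) next
        newp <- rbind(pr[-r, , drop = FALSE], sort(c(v, x)))
        p <- oracle_products(cx$strands, newp)
        if (is.null(p)) next
        res <- c(res, oracle_reaction_set("branch3", canonical_kernel(cx),
                                          list(p)))
      }
    }
  }
  sort(unique(res))
}

oracle_branch4 <- function(cx) {
  occ <- complex_occurrences(cx)
  pr <- complex_pairs(cx)
  res <- character(0)
  n <- NROW(pr)
  if (n < 2) return(res)
  off1 <- function(i, j) {
    if (occ$strand[i] != occ$strand[j]) return(NA_integer_)
    d <- occ$pos[j] - occ$pos[i]
    if (abs(d) == 1L) d else NA_integer_
  }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      e1 <- pr[a, ]; e2 <- pr[b, ]
      ori <- NULL
      if (occ$dom[e1[1]] == occ$dom[e2[1]]) ori <- c(e2[1], e2[2])
      else if (occ$dom[e1[1]] == occ$dom[e2[2]]) ori <- c(e2[2], e2[1])
      if (is.null(ori)) next
      A <- e1[1]; B <- e1[2]; C <- ori[1]; D <- ori[2]
      touch <- any(!is.na(c(off1(A, C), off1(A, D), off1(B, C), off1(B, D))))
      if (!touch) next
      helix <- FALSE                         # stacked rungs of one helix
      for (sw in list(c(C, D), c(D, C))) {
        d1 <- off1(A, sw[1]); d2 <- off1(B, sw[2])
        if (!is.na(d1) && !is.na(d2) && d1 == -d2) helix <- TRUE
      }
      if (helix) next
      newp <- rbind(pr[-c(a, b), , drop = FALSE],
                    sort(c(A, D)), sort(c(C, B)))
      p <- oracle_products(cx$strands, newp)
      if (is.null(p)) next
      res <- c(res, oracle_reaction_set("branch4", canonical_kernel(cx),
                                        list(p)))
    }
  }
  sort(unique(res))
}

move_strings <- function(moves) {
  sort(unique(vapply(moves, function(r) {
    sprintf("[%s] %s -> %s", r$rtype,
            paste(r$reactants, collapse = " + "),
            paste(r$products, collapse = " + "))
  }, character(1))))
}

# ---- graph metric oracles (exhaustive path enumeration) ------------------
oracle_betweenness <- function(g) {
  vn <- igraph::V(g)$name
  nb <- stats::setNames(rep(0, length(vn)), vn)
  eb <- new.env(parent = emptyenv())
  for (s in vn) {
    for (t in vn) {
      if (s == t) next
      paths <- igraph::all_simple_paths(g, from = s, to = t, mode = "out")
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      sp <- paths[lens == min(lens)]
      sigma <- length(sp)
      for (p in sp) {
        nm <- igraph::V(g)$name[p]
        if (length(nm) > 2) {
          for (v in nm[-c(1, length(nm))]) {
            nb[v] <- nb[v] + 1 / sigma
          }
        }
        for (i in seq_len(length(nm) - 1)) {
          k <- paste(nm[i], "->", nm[i + 1])
          eb[[k]] <- (if (is.null(eb[[k]])) 0 else eb[[k]]) + 1 / sigma
        }
      }
    }
  }
  ebv <- stats::setNames(
    vapply(ls(eb), function(k) eb[[k]], numeric(1)), ls(eb))
  list(node = nb, edge = ebv)
}

oracle_flow_hierarchy <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) return(NaN)
  on_cycle <- vapply(seq_len(nrow(el)), function(i) {
    u <- el[i, 1]; v <- el[i, 2]
    # edge is on a cycle iff v can reach u
    is.finite(igraph::distances(g, v = v, to = u, mode = "out")[1, 1])
  }, logical(1))
  mean(!on_cycle)
}

oracle_grc <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g, mode = "out")
  cr <- (rowSums(is.finite(d)) - 1) / (n - 1)
  sum(max(cr) - cr) / (n - 1)
}

oracle_clustering <- function(g) {
  gu <- igraph::as_undirected(g, mode = "collapse")
  A <- as.matrix(igraph::as_adjacency_matrix(gu))
  diag(A) <- 0
  n <- nrow(A)
  cc <- vapply(seq_len(n), function(v) {
    nbrs <- which(A[v, ] > 0)
    k <- length(nbrs)
    if (k < 2) return(0)
    sum(A[nbrs, nbrs]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
  list(mean = mean(cc), std = stats::sd(cc))
}

random_digraph <- function(n, m, seed) {
  set.seed(seed)
  all_e <- expand.grid(from = seq_len(n), to = seq_len(n))
  all_e <- all_e[all_e$from != all_e$to, ]
  sel <- all_e[sample.int(nrow(all_e), m), ]
  igraph::graph_from_data_frame(
    data.frame(from = paste0("v", sprintf("%02d", sel$from)),
               to = paste0("v", sprintf("%02d", sel$to))),
    directed = TRUE,
    vertices = data.frame(name = paste0("v", sprintf("%02d", seq_len(n)))))
}
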