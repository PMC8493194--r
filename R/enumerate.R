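#' @title CRN enumeration and condensation
#' @name enumerate
#' @description Breadth-first closure of the four reaction move generators
#'   over a starting strand set, with resting/transient classification and
#'   condensation of transient intermediates.
NULL

new_crn <- function(structures, reactions, initial, truncated, params,
                    condensed = FALSE) {
  structure(list(structures = structures, reactions = reactions,
                 initial = initial, truncated = truncated,
                 params = params, condensed = condensed),
            class = "dsd_crn")
}

#' @export
print.dsd_crn <- function(x, ...) {
  cat(sprintf("<dsd_crn%s> %d structures, %d reactions, %d initial%s\n",
              if (x$condensed) " condensed" else "",
              length(x$structures), length(x$reactions), length(x$initial),
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

reaction_is_uni <- function(r) length(r$reactants) == 1L

# Resting/transient classification. A complex is transient iff it has a
# unimolecular 1 -> 1 exit that leaves its SCC in the 1 -> 1 unimolecular
# reaction digraph (a one-way decay), or a spontaneous unimolecular
# dissociation (1 -> 2) exit *alongside at least one other unimolecular
# exit* (a fleeting on-pathway intermediate). A lone dissociation exit does
# not make a complex transient: a duplex held by a single weak domain is a
# resting species whose dissociation is an ordinary slow reaction.
# Everything else is resting. See the methods vignette for why this
# per-complex rule (rather than Peppercorn macrostate condensation) is used.
classify_resting <- function(kernels, reactions) {
  if (length(kernels) == 0) return(logical(0))
  idx <- stats::setNames(seq_along(kernels), kernels)
  edges <- integer(0)       # 1->1 uni edges, interleaved from/to
  has_split <- rep(FALSE, length(kernels))
  n_uni <- rep(0L, length(kernels))
  one_one <- list()
  for (r in reactions) {
    if (!reaction_is_uni(r)) next
    from <- unname(idx[r$reactants])
    if (is.na(from)) next
    n_uni[from] <- n_uni[from] + 1L
    if (length(r$products) >= 2) {
      has_split[from] <- TRUE
    } else {
      to <- unname(idx[r$products])
      if (!is.na(to) && to != from) {
        edges <- c(edges, from, to)
        one_one[[length(one_one) + 1L]] <- c(from, to)
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(kernels), directed = TRUE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  scc <- igraph::components(g, mode = "strong")$membership
  leaves_scc <- rep(FALSE, length(kernels))
  for (e in one_one) {
    if (scc[e[1]] != scc[e[2]]) leaves_scc[e[1]] <- TRUE
  }
  resting <- !(leaves_scc | (has_split & n_uni >= 2L))
  stats::setNames(resting, kernels)
}

#' Enumerate the reaction network of a strand set
#'
#' Seeds the working set with the single-strand complexes of `strands` and
#' repeatedly applies the four move generators (hybridization, dissociation,
#' three-way and four-way branch migration), canonicalizing products, until
#' a fixpoint or a cap fires (`truncated` is then set instead of raising).
#' When `params$transient_policy` is on, only resting complexes take part in
#' intermolecular binds and the returned CRN is condensed (see [condense()]);
#' pass `detailed = TRUE` for the detailed network.
#'
#' @param strands list of strands (character vectors of domain tokens).
#' @param domains named integer vector of base-domain lengths.
#' @param params an [enum_params()]; a NULL `release_cutoff` resolves to the
#'   maximum domain length in `domains`.
#' @param detailed return the detailed (uncondensed) CRN.
#' @return a `dsd_crn`.
#' @export
enumerate_crn <- function(strands, domains, params = enum_params(),
                          detailed = FALSE) {
  stopifnot(length(strands) >= 1)
  if (is.null(params$release_cutoff)) {
    params$release_cutoff <- max(domains)
  }
  structures <- list()      # canonical kernel -> dsd_complex
  reactions <- list()
  rkeys <- character(0)
  truncated <- FALSE
  uni_done <- character(0)  # kernels whose unimolecular moves were expanded
  pair_done <- character(0) # "k1 || k2" bimolecular attempts
  add_structure <- function(cx) {
    k <- canonical_kernel(cx)
    if (!is.null(structures[[k]])) return(TRUE)
    if (length(structures) >= params$max_structures) {
      truncated <<- TRUE
      return(FALSE)
    }
    structures[[k]] <<- cx
    TRUE
  }
  add_reaction <- function(r) {
    key <- reaction_key(r)
    if (key %in% rkeys) return(invisible(NULL))
    if (length(reactions) >= params$max_reactions) {
      truncated <<- TRUE
      return(invisible(NULL))
    }
    ok <- TRUE
    for (pk in unique(r$products)) {
      if (is.null(structures[[pk]])) {
        # product complexes were canonicalized by the move generators;
        # reparse from the kernel string to store them
        if (!add_structure(canonical_form(parse_kernel(pk, domains)))) {
          ok <- FALSE
        }
      }
    }
    if (!ok) return(invisible(NULL))
    rkeys <<- c(rkeys, key)
    reactions[[length(reactions) + 1L]] <<- r
    invisible(NULL)
  }
  initial <- character(0)
  for (s in strands) {
    cx <- canonical_form(new_complex(list(s)))
    add_structure(cx)
    initial <- c(initial, canonical_kernel(cx))
  }
  initial <- sort(unique(initial))

  repeat {
    # --- unimolecular closure ---
    repeat {
      todo <- sort(setdiff(names(structures), uni_done))
      if (length(todo) == 0) break
      for (k in todo) {
        cx <- structures[[k]]
        moves <- c(bind_moves(cx, NULL, params),
                   open_moves(cx, domains, params),
                   branch3_moves(cx, params),
                   branch4_moves(cx, params))
        for (r in moves) add_reaction(r)
        uni_done <- c(uni_done, k)
      }
    }
    # --- classification, then bimolecular binds ---
    kernels <- sort(names(structures))
    resting <- classify_resting(kernels, reactions)
    eligible <- if (params$transient_policy) kernels[resting[kernels]] else kernels
    grew <- FALSE
    n_before_s <- length(structures)
    n_before_r <- length(reactions)
    for (i in seq_along(eligible)) {
      for (j in i:length(eligible)) {
        if (j > length(eligible)) break
        key <- paste(eligible[i], "||", eligible[j])
        if (key %in% pair_done) next
        pair_done <- c(pair_done, key)
        a <- structures[[eligible[i]]]
        b <- structures[[eligible[j]]]
        if (complex_size(a) + complex_size(b) > params$max_complex_size) next
        for (r in bind_moves(a, b, params)) add_reaction(r)
      }
    }
    if (length(structures) == n_before_s && length(reactions) == n_before_r) {
      break
    }
  }

  crn <- new_crn(structures[sort(names(structures))], reactions, initial,
                 truncated, params, condensed = FALSE)
  if (params$transient_policy && !detailed) condense(crn) else crn
}

#' Condense a detailed CRN
#'
#' Transient complexes (see the classification rule in the package vignette:
#' spontaneous dissociation exits or one-way unimolecular decay) are
#' collapsed: reactions whose reactants are all kept (resting complexes plus
#' the initial strands) are rerouted through the fate multisets of their
#' transient products; reactions initiated by non-source transients are
#' dropped, as are no-ops.
#'
#' @param crn a detailed `dsd_crn`.
#' @return a condensed `dsd_crn`.
#' @export
condense <- function(crn) {
  if (crn$condensed) return(crn)
  kernels <- sort(names(crn$structures))
  resting <- classify_resting(kernels, crn$reactions)
  kept <- kernels[resting[kernels] | kernels %in% crn$initial]
  uni_from <- split(
    Filter(reaction_is_uni, crn$reactions),
    vapply(Filter(reaction_is_uni, crn$reactions),
           function(r) r$reactants, character(1))
  )
  memo <- new.env(parent = emptyenv())
  fates <- function(k, visiting = character(0)) {
    if (resting[[k]]) return(list(k))
    if (!is.null(memo[[k]])) return(memo[[k]])
    if (k %in% visiting) return(list())        # cycle guard
    visiting <- c(visiting, k)
    res <- list()
    for (r in uni_from[[k]] %||% list()) {
      combos <- list(character(0))
      for (pk in r$products) {
        pf <- fates(pk, visiting)
        if (length(pf) == 0) { combos <- list(); break }
        combos <- unlist(lapply(combos, function(cm) {
          lapply(pf, function(f) sort(c(cm, f)))
        }), recursive = FALSE)
      }
      res <- c(res, combos)
    }
    res <- unique(res)
    if (length(res) == 0) res <- list(k)       # isolated transient: keep
    memo[[k]] <- res
    res
  }
  out_reactions <- list()
  out_keys <- character(0)
  for (r in crn$reactions) {
    if (!all(r$reactants %in% kept)) next
    combos <- list(character(0))
    for (pk in r$products) {
      pf <- fates(pk)
      combos <- unlist(lapply(combos, function(cm) {
        lapply(pf, function(f) sort(c(cm, f)))
      }), recursive = FALSE)
    }
    for (prods in unique(combos)) {
      rr <- new_reaction(r$rtype, r$reactants, prods)
      if (is_noop_reaction(rr)) next
      key <- reaction_key(rr)
      if (key %in% out_keys) next
      out_keys <- c(out_keys, key)
      out_reactions[[length(out_reactions) + 1L]] <- rr
    }
  }
  keep_kernels <- sort(unique(c(
    kept,
    unlist(lapply(out_reactions, function(r) c(r$reactants, r$products)))
  )))
  new_crn(crn$structures[keep_kernels], out_reactions, crn$initial,
          crn$truncated, crn$params, condensed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary metrics of a CRN
#'
#' @param crn a `dsd_crn` (condensed counts are what the exploration layer
#'   consumes by default).
#' @return list with `n_structures`, `n_reactions`, `mss` (mean strand count
#'   over structures) and `ert` (Shannon entropy, base 2, of the reaction
#'   type distribution; 0 when there is at most one reaction).
#' @export
crn_metrics <- function(crn) {
  stopifnot(length(crn$structures) >= 1)
  sizes <- vapply(crn$structures, complex_size, integer(1))
  n_r <- length(crn$reactions)
  ert <- 0
  if (n_r > 1) {
    tab <- table(vapply(crn$reactions, function(r) r$rtype, character(1)))
    p <- as.numeric(tab) / n_r
    ert <- -sum(p * log2(p))
  }
  list(n_structures = length(crn$structures), n_reactions = n_r,
       mss = mean(sizes), ert = ert)
}

#' Serialize / deserialize a CRN as JSON
#'
#' @param crn a `dsd_crn`.
#' @param path file path.
#' @return `write_crn_json` invisibly returns `path`; `read_crn_json`
#'   returns the `dsd_crn` (structures reparsed from kernel strings).
#' @export
write_crn_json <- function(crn, path) {
  doc <- list(
    condensed = crn$condensed,
    truncated = crn$truncated,
    initial = crn$initial,
    structures = names(crn$structures),
    reactions = lapply(crn$reactions, function(r) {
      list(rtype = r$rtype, reactants = r$reactants, products = r$products)
    }),
    params = crn$params[c("max_complex_size", "release_cutoff",
                          "max_structures", "max_reactions",
                          "transient_policy")]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_crn_json
#' @param domains named integer vector of base-domain lengths used to
#'   reparse structures.
#' @export
read_crn_json <- function(path, domains = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  kernels <- unlist(doc$structures)
  structures <- stats::setNames(
    lapply(kernels, function(k) canonical_form(parse_kernel(k, domains))),
    kernels)
  reactions <- lapply(doc$reactions, function(r) {
    new_reaction(r$rtype, unlist(r$reactants), unlist(r$products))
  })
  p <- doc$params
  params <- enum_params(p$max_complex_size, p$release_cutoff,
                        p$max_structures, p$max_reactions,
                        p$transient_policy)
  new_crn(structures, reactions, unlist(doc$initial),
          isTRUE(doc$truncated), params, condensed = isTRUE(doc$condensed))
}

#' Write a CRN as kernel/PIL-style text
#'
#' Species lines `s<i> = <kernel>` followed by `reaction [type] reactants ->
#' products` lines (species referenced by kernel string).
#'
#' @param crn a `dsd_crn`.
#' @param domains named integer vector of base-domain lengths.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_crn_pil <- function(crn, domains, path) {
  kernels <- names(crn$structures)
  lines <- c(
    sprintf("length %s = %d", names(domains), as.integer(domains)),
    sprintf("s%d = %s", seq_along(kernels), kernels),
    vapply(crn$reactions, function(r) {
      sprintf("# reaction [%s] %s -> %s", r$rtype,
              paste(r$reactants, collapse = " + "),
              paste(r$products, collapse = " + "))
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
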