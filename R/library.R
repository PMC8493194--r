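#' Specify an (n, m) strand library
#'
#' An (n, m) library is the exhaustive list of strands with `n` domains,
#' each drawn from `m` base domain types and their complements (2m tokens
#' per position), giving (2m)^n distinct ordered strands.
#'
#' @param n domains per strand (>= 1).
#' @param domain_lengths named integer vector: base domain name -> nucleotide
#'   length.
#' @param name label for the library.
#' @return an object of class `library_spec`.
#' @export
library_spec <- function(n, domain_lengths, name = "custom") {
  stopifnot(n >= 1, length(domain_lengths) >= 1, all(domain_lengths > 0),
            !is.null(names(domain_lengths)),
            !anyDuplicated(names(domain_lengths)))
  structure(list(n = as.integer(n),
                 domain_lengths = vapply(domain_lengths, as.integer,
                                         integer(1)),
                 name = name),
            class = "library_spec")
}

#' Built-in library presets
#'
#' L1: 2 domains per strand, domains a, b of 10 nt (16 strands).
#' L2: 4 domains per strand, domains a, b of 5 nt (256 strands).
#' L3: 3 domains per strand, domains a, b, c, e, f of 17 nt and d of 15 nt
#' (1728 strands).
#'
#' @param name one of "L1", "L2", "L3".
#' @return a `library_spec`.
#' @export
library_preset <- function(name = c("L1", "L2", "L3")) {
  name <- match.arg(name)
  switch(name,
    L1 = library_spec(2, c(a = 10L, b = 10L), "L1"),
    L2 = library_spec(4, c(a = 5L, b = 5L), "L2"),
    L3 = library_spec(3, c(a = 17L, b = 17L, c = 17L, d = 15L,
                           e = 17L, f = 17L), "L3")
  )
}

#' Build the exhaustive strand library for a spec
#'
#' Enumerates all (2m)^n ordered domain tuples as strands, sorted
#' lexicographically by domain tokens (enumeration order is stable across
#' runs; genome bit positions index into it).
#'
#' @param spec a `library_spec`.
#' @param max_size overflow guard on (2m)^n.
#' @return an object of class `strand_library` with fields `spec`, `strands`
#'   (list of character vectors) and `strand_ids`.
#' @export
build_library <- function(spec, max_size = 100000L) {
  stopifnot(inherits(spec, "library_spec"))
  base <- names(spec$domain_lengths)
  tokens <- sort(c(base, paste0(base, "*")))
  n_strands <- length(tokens)^spec$n
  if (n_strands > max_size) {
    stop(sprintf("library size (2m)^n = %.0f exceeds cap %d",
                 n_strands, max_size))
  }
  grid <- do.call(expand.grid,
                  c(rev(replicate(spec$n, tokens, simplify = FALSE)),
                    list(stringsAsFactors = FALSE)))
  # expand.grid varies the first column fastest; reversing the inputs and
  # the columns yields lexicographic order over domain tuples
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  strands <- lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ])))
  ids <- vapply(strands, paste, character(1), collapse = " ")
  ord <- order(ids, method = "radix")
  structure(list(spec = spec, strands = strands[ord],
                 strand_ids = ids[ord]),
            class = "strand_library")
}

#' Number of non-empty strand subsets of a library
#'
#' @param library a `strand_library`.
#' @return 2^|strands| - 1 (numeric; exact only while representable, which
#'   covers the presets used for reporting: L1 has 65535).
#' @export
subset_count <- function(library) {
  2^length(library$strands) - 1
}

#' Construct a genome (strand-subset membership vector)
#'
#' @param bits logical (or 0/1) vector of length |strands|.
#' @param max_strands cap on the number of selected strands (default 7).
#' @return an object of class `dsd_genome`.
#' @export
new_genome <- function(bits, max_strands = 7L) {
  bits <- as.logical(bits)
  stopifnot(!anyNA(bits))
  g <- structure(list(bits = bits, max_strands = as.integer(max_strands)),
                 class = "dsd_genome")
  validate_genome(g)
  g
}

#' @rdname new_genome
#' @param g a `dsd_genome`.
#' @export
validate_genome <- function(g) {
  k <- sum(g$bits)
  if (k < 1) stop("genome selects no strand")
  if (k > g$max_strands) {
    stop(sprintf("genome selects %d strands, cap is %d", k, g$max_strands))
  }
  invisible(TRUE)
}

#' Strands selected by a genome
#'
#' @param g a `dsd_genome`.
#' @param library a `strand_library` with |strands| = length(g$bits).
#' @return list of strands (character vectors) in library order.
#' @export
genome_to_strands <- function(g, library) {
  stopifnot(inherits(g, "dsd_genome"), inherits(library, "strand_library"))
  if (length(g$bits) != length(library$strands)) {
    stop("genome length does not match library size")
  }
  validate_genome(g)
  library$strands[g$bits]
}

#' Write a library manifest as CSV
#' @param library a `strand_library`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_library_csv <- function(library, path) {
  utils::write.csv(
    data.frame(index = seq_along(library$strands),
               strand = library$strand_ids),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.strand_library <- function(x, ...) {
  cat(sprintf("<strand_library %s> n=%d, %d domain types, %d strands\n",
              x$spec$name, x$spec$n, length(x$spec$domain_lengths),
              length(x$strands)))
  invisible(x)
}
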