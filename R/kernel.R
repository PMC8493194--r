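#' Parse a kernel-notation string into a complex
#'
#' Kernel notation writes a multistranded complex on one line: a domain
#' token (`a`, `b*`, ...) optionally followed immediately by `(` opens a
#' helix; a bare `)` closes the most recent open helix and stands for the
#' complement of the opening domain; `+` separates strands. Example:
#' `"a( a*( + ) )"` is the two-strand duplex of `a a*` with itself.
#' Explicit closer names (`)x*` or `x*)` dialects) are accepted and checked
#' against the implied complement.
#'
#' @param text kernel string.
#' @param domains optional named integer vector of base-domain lengths used
#'   to reject unknown domain names.
#' @return a `dsd_complex`.
#' @export
parse_kernel <- function(text, domains = NULL) {
  raw <- strsplit(trimws(text), "\\s+")[[1]]
  raw <- raw[nzchar(raw)]
  strands <- list()
  cur <- character(0)
  occ_dom <- character(0)
  stack <- integer(0)      # global occurrence indices of open helices
  pairs <- NULL
  n_occ <- 0L
  perr <- function(i, msg) {
    stop(sprintf("kernel parse error at token %d ('%s'): %s", i, raw[i], msg),
         call. = FALSE)
  }
  push_occ <- function(d) {
    if (!is.null(domains) && !(dom_base(d) %in% names(domains))) {
      stop(sprintf("unknown domain name '%s'", d), call. = FALSE)
    }
    cur[length(cur) + 1L] <<- d
    n_occ <<- n_occ + 1L
    occ_dom[n_occ] <<- d
    n_occ
  }
  for (i in seq_along(raw)) {
    tok <- raw[i]
    if (tok == "+") {
      if (length(cur) == 0) perr(i, "empty strand before '+'")
      strands[[length(strands) + 1L]] <- cur
      cur <- character(0)
    } else if (tok == ")" || grepl("^\\)", tok) || grepl("\\)$", tok)) {
      if (length(stack) == 0) perr(i, "unbalanced ')'")
      opener <- stack[length(stack)]
      stack <- stack[-length(stack)]
      implied <- dom_complement(occ_dom[opener])
      name <- gsub("[()]", "", tok)
      if (nzchar(name) && dom_normalize(name) != implied) {
        perr(i, sprintf("closer '%s' is not the complement of opener '%s'",
                        name, occ_dom[opener]))
      }
      j <- push_occ(implied)
      pairs <- rbind(pairs, c(opener, j))
    } else if (grepl("\\($", tok)) {
      d <- dom_normalize(sub("\\($", "", tok))
      if (!nzchar(d)) perr(i, "'(' must follow a domain name")
      stack <- c(stack, push_occ(d))
    } else {
      push_occ(dom_normalize(tok))
    }
  }
  if (length(stack) > 0) {
    stop("kernel parse error: unbalanced '(' (", length(stack),
         " unclosed)", call. = FALSE)
  }
  if (length(cur) == 0) stop("kernel parse error: empty final strand",
                             call. = FALSE)
  strands[[length(strands) + 1L]] <- cur
  new_complex(strands, pairs)
}

#' Write a complex in kernel notation
#'
#' Inverse of [parse_kernel()]: openers are written `d(`, closers `)`, and
#' strands are joined by `+`. `write_kernel` serializes the stored strand
#' order; use [canonical_kernel()] for the rotation-invariant string.
#'
#' @param cx a `dsd_complex`.
#' @return kernel string.
#' @export
write_kernel <- function(cx) {
  occ <- complex_occurrences(cx)
  p <- cx$pairing
  toks <- character(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    if (is.na(p[i])) {
      toks[i] <- occ$dom[i]
    } else if (p[i] > i) {
      toks[i] <- paste0(occ$dom[i], "(")
    } else {
      toks[i] <- ")"
    }
  }
  per_strand <- split(toks, occ$strand)
  paste(vapply(per_strand, paste, character(1), collapse = " "),
        collapse = " + ")
}

#' Read complexes from a kernel/PIL-style text file
#'
#' One complex per line as `name = <kernel string>`; domain declarations as
#' `length x = N`; `#` starts a comment. UTF-8.
#'
#' @param path file path.
#' @return list with `domains` (named integer vector) and `complexes`
#'   (named list of `dsd_complex`).
#' @export
read_pil <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  domains <- integer(0)
  complexes <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^length\\s+(\\S+)\\s*=\\s*(\\d+)$", ln))[[1]]
    if (length(m) == 3) {
      domains[dom_base(m[2])] <- as.integer(m[3])
      next
    }
    m <- regmatches(ln, regexec("^(\\S+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) == 3) {
      complexes[[m[2]]] <- parse_kernel(
        m[3], domains = if (length(domains)) domains else NULL)
      next
    }
    stop("unparseable PIL line: ", ln)
  }
  list(domains = domains, complexes = complexes)
}

#' Write complexes to a kernel/PIL-style text file
#'
#' @param complexes named list of `dsd_complex`.
#' @param domains named integer vector of base-domain lengths.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_pil <- function(complexes, domains, path) {
  lines <- c(
    sprintf("length %s = %d", names(domains), as.integer(domains)),
    sprintf("%s = %s", names(complexes),
            vapply(complexes, write_kernel, character(1)))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
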