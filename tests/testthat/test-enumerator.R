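test_that("bind_moves finds the Fig-1 hairpin and duplex binds", {
  doms <- toy_domains()
  s <- canonical_form(parse_kernel("a a*", doms))
  intra <- bind_moves(s, NULL, fig1_params())
  expect_equal(move_strings(intra), "[bind] a a* -> a( )")

  inter <- bind_moves(s, s, fig1_params())
  expect_equal(length(inter), 1L)  # symmetric binds collapse to one
  expect_equal(inter[[1]]$reactants, c("a a*", "a a*"))
  expect_equal(inter[[1]]$products, "a a*( + ) a*")

  # orthogonal strands: no move
  ab <- canonical_form(parse_kernel("a b", c(a = 10L, b = 10L)))
  cd <- canonical_form(parse_kernel("c d", c(c = 10L, d = 10L)))
  expect_equal(bind_moves(ab, cd, fig1_params(4)), list())
})

test_that("open_moves respects the release cutoff and splits products", {
  doms <- toy_domains()
  h <- canonical_form(parse_kernel("a( )", doms))
  expect_equal(move_strings(open_moves(h, doms, fig1_params())),
               "[open] a( ) -> a a*")
  # cutoff below the domain length gates the move
  expect_equal(open_moves(h, doms, enum_params(release_cutoff = 9)), list())

  d <- canonical_form(parse_kernel("a( a*( + ) )", doms))
  got <- move_strings(open_moves(d, doms, fig1_params()))
  # each single-pair opening yields the same connected 2-strand intermediate
  expect_equal(got, "[open] a( a*( + ) ) -> a a*( + ) a*")
})

test_that("branch3_moves handles displacement, hairpins and no-ops", {
  # textbook toehold-mediated displacement: invader [t x] held by toehold,
  # substrate [x* t*], incumbent [x]
  cx <- canonical_form(crnscape:::find_noncrossing_order(
    list(c("t", "x"), c("x*", "t*"), "x"), rbind(c(1, 4), c(5, 3))))
  mv <- branch3_moves(cx)
  expect_equal(move_strings(mv),
               sprintf("[branch3] %s -> %s + %s", canonical_kernel(cx),
                       "t( x( + ) )", "x"))
  expect_equal(branch3_moves(canonical_form(parse_kernel("a( )"))), list())
  # symmetric displacement that regenerates an isomorphic complex:
  # incumbent and invader are both bare "x" strands
  sym <- canonical_form(crnscape:::find_noncrossing_order(
    list(c("t", "x"), c("x*", "t*"), "x", "x"),
    rbind(c(1, 4), c(5, 3), c(2, 6))))
  # moves exchanging the two x strands yield identical reactant/product
  # multisets and are suppressed; allowed moves (if any) must differ
  for (r in branch3_moves(sym)) {
    expect_false(identical(sort(r$reactants), sort(r$products)))
  }
})

test_that("branch4_moves needs a genuine junction", {
  doms <- c(a = 10L, b = 10L, c = 10L)
  hx <- canonical_form(parse_kernel("a( a( + ) c + ) b", doms))
  mv <- branch4_moves(hx)
  expect_equal(move_strings(mv),
               "[branch4] a( a( + ) c + ) b -> a( a( + ) b + ) c")
  # < 2 pairs of one domain type
  expect_equal(branch4_moves(canonical_form(parse_kernel("a( b( + ) )"))),
               list())
  # stacked duplex helix is not a junction
  expect_equal(branch4_moves(canonical_form(parse_kernel("a( a*( + ) )"))),
               list())
})

test_that("enumerate_crn reproduces the hand-enumerated small systems", {
  doms <- toy_domains()
  fig1 <- enumerate_crn(list(c("a", "a*")), doms, fig1_params())
  expect_equal(length(fig1$structures), 3L)
  expect_equal(length(fig1$reactions), 4L)
  expect_false(fig1$truncated)

  mono <- enumerate_crn(list(c("a", "b")), c(a = 10L, b = 10L),
                        fig1_params())
  expect_equal(length(mono$structures), 1L)
  expect_equal(length(mono$reactions), 0L)

  two <- enumerate_crn(list("a", "a*"), doms, fig1_params())
  expect_equal(length(two$structures), 3L)
  expect_equal(reaction_strings(two),
               c("[bind] a + a* -> a( + )", "[open] a( + ) -> a + a*"))
})

test_that("condense matches the SCC/fate oracle cases", {
  # identity on a CRN where every complex is resting
  doms <- c(a = 10L, b = 10L)
  crn <- enumerate_crn(list(c("a", "b")), doms, fig1_params(), detailed = TRUE)
  cc <- condense(crn)
  expect_equal(names(cc$structures), names(crn$structures))

  # chain A -> B -> C of fast 1 -> 1 reactions: A kept as source, B gone
  chain <- crnscape:::new_crn(
    structures = stats::setNames(vector("list", 3), c("A", "B", "C")),
    reactions = list(crnscape:::new_reaction("branch3", "A", "B"),
                     crnscape:::new_reaction("branch3", "B", "C")),
    initial = "A", truncated = FALSE, params = enum_params(),
    condensed = FALSE)
  cc2 <- condense(chain)
  expect_setequal(names(cc2$structures), c("A", "C"))
  expect_equal(reaction_strings(cc2), "[branch3] A -> C")

  # Fig 1: the one-pair intermediate condenses away, duplex reaction 2s -> d
  detailed <- enumerate_crn(list(c("a", "a*")), toy_domains(), fig1_params(),
                            detailed = TRUE)
  expect_true("a a*( + ) a*" %in% names(detailed$structures))
  cond <- condense(detailed)
  expect_false("a a*( + ) a*" %in% names(cond$structures))
  expect_true("[bind] a a* + a a* -> a( a*( + ) )" %in%
                reaction_strings(cond))
})

test_that("crn_metrics computes MSS and ERT", {
  fig1 <- enumerate_crn(list(c("a", "a*")), toy_domains(), fig1_params())
  m <- crn_metrics(fig1)
  expect_equal(m$n_structures, 3L)
  expect_equal(m$mss, 4 / 3)
  expect_equal(m$ert, 1.0)  # bind and open in equal counts

  mk <- function(types) {
    crnscape:::new_crn(
      structures = stats::setNames(list(parse_kernel("a a*")), "a a*"),
      reactions = lapply(seq_along(types), function(i) {
        crnscape:::new_reaction(types[i], paste0("r", i), paste0("p", i))
      }),
      initial = "a a*", truncated = FALSE, params = enum_params(),
      condensed = TRUE)
  }
  expect_equal(crn_metrics(mk(c("bind", "open")))$ert, 1.0)
  expect_equal(crn_metrics(mk(c("bind", "open", "branch3", "branch4")))$ert,
               2.0)
  expect_equal(crn_metrics(mk("bind"))$ert, 0)
})

test_that("strand multisets are conserved across every reaction", {
  doms <- toy_domains()
  lib <- toy_library()
  strand_multiset <- function(kernels) {
    sort(unlist(lapply(kernels, function(k) {
      vapply(parse_kernel(k, doms)$strands, paste, character(1),
             collapse = " ")
    })))
  }
  for (sel in list(2L, c(1L, 4L), c(2L, 3L))) {
    crn <- enumerate_crn(lib$strands[sel], doms, fig1_params(3),
                         detailed = TRUE)
    for (r in crn$reactions) {
      expect_equal(strand_multiset(r$reactants), strand_multiset(r$products))
    }
  }
})

test_that("binds are reversible when the cutoff covers all domains", {
  doms <- toy_domains()
  crn <- enumerate_crn(list(c("a", "a*"), c("a*", "a")), doms,
                       fig1_params(3), detailed = TRUE)
  keys <- reaction_strings(crn)
  for (r in crn$reactions) {
    if (r$rtype != "bind") next
    back <- sprintf("[open] %s -> %s", paste(r$products, collapse = " + "),
                    paste(r$reactants, collapse = " + "))
    expect_true(back %in% keys, label = back)
  }
})

test_that("raising max_complex_size only adds structures", {
  doms <- toy_domains()
  for (strands in list(list(c("a", "a*")), list(c("a", "a"), c("a*", "a*")))) {
    small <- enumerate_crn(strands, doms, fig1_params(2), detailed = TRUE)
    large <- enumerate_crn(strands, doms, fig1_params(3), detailed = TRUE)
    expect_true(all(names(small$structures) %in% names(large$structures)))
  }
})

test_that("enumeration is deterministic and caps set the truncated flag", {
  doms <- toy_domains()
  strands <- list(c("a", "a"), c("a*", "a*"))
  a <- enumerate_crn(strands, doms, fig1_params(3))
  b <- enumerate_crn(strands, doms, fig1_params(3))
  fa <- withr::local_tempfile(fileext = ".json")
  fb <- withr::local_tempfile(fileext = ".json")
  write_crn_json(a, fa)
  write_crn_json(b, fb)
  expect_identical(readLines(fa), readLines(fb))

  capped <- enumerate_crn(strands, doms,
                          enum_params(max_complex_size = 6,
                                      release_cutoff = 10,
                                      max_structures = 4),
                          detailed = TRUE)
  expect_true(capped$truncated)
})

test_that("move generators agree with the exhaustive rewrite oracle", {
  doms <- toy_domains()
  lib <- toy_library()
  params <- fig1_params(3)
  subsets <- c(lapply(1:4, function(i) i),
               utils::combn(4, 2, simplify = FALSE))
  seen <- character(0)
  for (sel in subsets) {
    crn <- enumerate_crn(lib$strands[sel], doms, params, detailed = TRUE)
    kernels <- setdiff(names(crn$structures), seen)
    seen <- c(seen, kernels)
    for (k in kernels) {
      cx <- crn$structures[[k]]
      expect_equal(move_strings(bind_moves(cx, NULL, params)),
                   oracle_bind_intra(cx), label = paste("intra bind", k))
      expect_equal(move_strings(open_moves(cx, doms, params)),
                   oracle_open(cx, doms, params$release_cutoff),
                   label = paste("open", k))
      expect_equal(move_strings(branch3_moves(cx, params)),
                   oracle_branch3(cx), label = paste("branch3", k))
      expect_equal(move_strings(branch4_moves(cx, params)),
                   oracle_branch4(cx), label = paste("branch4", k))
    }
    # intermolecular binds between the initial single strands
    singles <- lapply(crn$initial, function(k) crn$structures[[k]])
    for (i in seq_along(singles)) {
      for (j in i:length(singles)) {
        expect_equal(
          move_strings(bind_moves(singles[[i]], singles[[j]], params)),
          oracle_bind_inter(singles[[i]], singles[[j]],
                            params$max_complex_size),
          label = paste("inter bind", crn$initial[i], "+", crn$initial[j]))
      }
    }
  }
})

test_that("CRN JSON round-trips", {
  doms <- toy_domains()
  crn <- enumerate_crn(list(c("a", "a*")), doms, fig1_params())
  path <- withr::local_tempfile(fileext = ".json")
  write_crn_json(crn, path)
  back <- read_crn_json(path, doms)
  expect_equal(names(back$structures), names(crn$structures))
  expect_equal(reaction_strings(back), reaction_strings(crn))
  expect_equal(back$initial, crn$initial)
})
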