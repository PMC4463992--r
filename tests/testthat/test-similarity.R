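# Helpers building profiles with prescribed per-shell counts.
profile_from_counts <- function(counts, scheme) {
  bounds <- c(0, scheme$breakpoints)
  radii <- unlist(lapply(seq_along(counts), function(i) {
    rep(bounds[i] + 0.5, counts[i])
  }))
  layer_profile(radii, scheme)
}

toy2 <- layer_scheme(10)  # two shells: [0,10) and [10, Inf)

test_that("shell assignment uses half-open intervals over the default ten shells", {
  sch <- default_layer_scheme()
  expect_equal(sch$n_shells, 10L)
  expect_equal(sch$breakpoints, c(10, 20, 30, 40, 50, 60, 70, 80, 100))
  p <- layer_profile(c(1, 2, 3), sch)
  expect_equal(p$counts, c(3L, rep(0L, 9L)))
  expect_equal(shell_index(10, sch), 2L)       # boundary goes outward
  expect_equal(shell_index(0, sch), 1L)
  expect_equal(shell_index(100, sch), 10L)
  expect_equal(shell_index(250, sch), 10L)
  expect_error(shell_index(-1, sch), "non-negative")

  set.seed(1)
  radii <- runif(1000, 0, 120)
  expect_equal(layer_profile(radii, sch)$counts,
               oracle_shell_counts(radii, sch$breakpoints))
  expect_equal(sum(layer_profile(radii, sch)$counts), 1000L)
})

test_that("per-layer similarity follows the relative-difference formula with the empty-shell convention", {
  p_a <- profile_from_counts(c(10, 0), toy2)
  p_b <- profile_from_counts(c(5, 0), toy2)
  p_c <- profile_from_counts(c(25, 7), toy2)
  expect_equal(per_layer_similarity(p_a, p_a), c(1, 1))
  expect_equal(per_layer_similarity(p_a, p_b)[1], 0.5)
  expect_equal(per_layer_similarity(p_a, p_c), c(-0.5, 0))   # l1=0,l2=7 -> 0
  expect_equal(per_layer_similarity(p_a, p_b)[2], 1)         # 0 vs 0 -> 1
  expect_error(per_layer_similarity(p_a, layer_profile(1, layer_scheme(5))),
               "different layer schemes")
})

test_that("layer weights average the two count fractions and always sum to one", {
  p1 <- profile_from_counts(c(6, 4), toy2)
  expect_equal(layer_weights(p1, p1), c(0.6, 0.4))
  set.seed(2)
  for (i in 1:20) {
    c1 <- rpois(2, 20) + 1L
    c2 <- rpois(2, 20) + 1L
    q1 <- profile_from_counts(c1, toy2)
    q2 <- profile_from_counts(c2, toy2)
    w <- layer_weights(q1, q2)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, oracle_layer_weights(c1, c2), tolerance = 1e-12)
  }
})

test_that("density similarity is the weighted per-shell sum and is one at identity", {
  g <- make_structure(structure_spec(n_atoms = 300L, seed = 5L))
  expect_equal(density_similarity(g$structure, g$structure), 1, tolerance = 1e-12)

  p1 <- profile_from_counts(c(5, 5), toy2)
  p2 <- profile_from_counts(c(5, 10), toy2)
  # hand-computed: sims (1, 0), weights ((1/2+1/3)/2, (1/2+2/3)/2) = (5/12, 7/12)
  expect_equal(density_similarity(p1, p2, toy2), 5 / 12, tolerance = 1e-12)

  moved <- perturb_structure(g$structure, 0.1, seed = 6)
  expect_lt(density_similarity(g$structure, moved), 1)
})

test_that("scalar similarity is the unclamped relative difference", {
  expect_equal(scalar_similarity(100, 100), 1)
  expect_equal(scalar_similarity(100, 150), 0.5)
  expect_equal(scalar_similarity(100, 250), -0.5)
  expect_error(scalar_similarity(0, 5), "positive")
  expect_error(scalar_similarity(10, -1), "non-negative")
  # invariance to scaling both arguments by a positive factor
  set.seed(3)
  for (i in 1:20) {
    n1 <- runif(1, 1, 100); n2 <- runif(1, 0, 200); k <- runif(1, 0.1, 10)
    expect_equal(scalar_similarity(n1, n2), scalar_similarity(k * n1, k * n2),
                 tolerance = 1e-12)
    expect_equal(scalar_similarity(n1, n1), 1, tolerance = 1e-12)
  }
})

test_that("atom, residue, residue-type counts and element fractions are bookkeeping-exact", {
  tiny <- protein_structure("tiny", data.frame(
    element = c("N", "C", "C"), x = c(0, 1, 2), y = 0, z = 0,
    resname = "GLY", resno = 1L, chain = "A"))
  expect_equal(c(count_atoms(tiny), count_residues(tiny), count_residue_types(tiny)),
               c(3L, 1L, 1L))

  two_res <- protein_structure("two", data.frame(
    element = rep(c("C", "C", "N", "O"), 2), x = 1:8, y = 0, z = 0,
    resname = rep(c("ALA", "GLY"), each = 4), resno = rep(1:2, each = 4),
    chain = "A"))
  expect_equal(c(count_atoms(two_res), count_residues(two_res), count_residue_types(two_res)),
               c(8L, 2L, 2L))
  expect_equal(element_fraction(two_res, "C"), 0.5)
  expect_equal(element_fraction(two_res, "N"), 0.25)

  allc <- protein_structure("c", data.frame(
    element = "C", x = 1:4, y = 0, z = 0, resname = "ALA", resno = 1L, chain = "A"))
  expect_equal(element_fraction(allc, "C"), 1)

  g <- make_structure(structure_spec(n_atoms = 777L, n_residues = 90L, seed = 8L))
  expect_equal(count_atoms(g$structure), 777L)
  expect_equal(count_residues(g$structure), g$truth$n_residues)
  expect_equal(count_residue_types(g$structure), g$truth$n_residue_types)
  for (el in names(g$truth$element_counts)) {
    expect_equal(element_fraction(g$structure, el),
                 g$truth$element_counts[[el]] / 777)
  }
})

test_that("the P/S positional rule scores same, adjacent and distant shells as 1.0, 0.8 and 0", {
  mk <- function(shell, seed) {
    frac <- rep(0, 10); frac[c(1, 3, 4, 5)] <- 0.25
    make_structure(structure_spec(
      n_atoms = 200L, shell_fractions = frac,
      elements = c(C = 0.99, S = 0.01), pin_elements = c(S = shell),
      seed = seed))$structure
  }
  expect_equal(element_position_similarity(mk(3, 1), mk(3, 2), "S"), 1.0)
  expect_equal(element_position_similarity(mk(3, 1), mk(4, 2), "S"), 0.8)
  expect_equal(element_position_similarity(mk(1, 1), mk(5, 2), "S"), 0.0)
  # absence handling: no P anywhere -> 1; P in exactly one -> 0
  expect_equal(element_position_similarity(mk(3, 1), mk(4, 2), "P"), 1.0)
  withP <- make_structure(structure_spec(
    n_atoms = 200L, shell_fractions = c(rep(0.25, 4), rep(0, 6)),
    elements = c(C = 0.98, P = 0.02), pin_elements = c(P = 2), seed = 3))$structure
  expect_equal(element_position_similarity(mk(3, 1), withP, "P"), 0.0)
  expect_error(element_position_similarity(mk(3, 1), withP, "C"), "P and S")
})

test_that("multiple sparse atoms score by the best-matching pair", {
  frac <- rep(0, 10); frac[c(2, 5)] <- 0.5
  multi <- make_structure(structure_spec(
    n_atoms = 300L, shell_fractions = frac,
    elements = c(C = 0.9, S = 0.1), seed = 4))$structure
  frac2 <- rep(0, 10); frac2[5] <- 1
  single <- make_structure(structure_spec(
    n_atoms = 100L, shell_fractions = frac2,
    elements = c(C = 0.99, S = 0.01), pin_elements = c(S = 5), seed = 5))$structure
  # multi has S spread over shells 2 and 5; one of them matches shell 5 exactly
  expect_equal(element_position_similarity(multi, single, "S"), 1.0)
})

test_that("the nine-parameter vector assembles the component similarities", {
  g1 <- make_structure(structure_spec(n_atoms = 400L, seed = 10L))
  g2 <- make_structure(structure_spec(n_atoms = 550L, seed = 11L))
  s1 <- g1$structure; s2 <- g2$structure
  v <- parameter_vector(s1, s2)
  expect_named(v, paste0("s", 1:9))
  # element-wise recomputation from first principles
  r1 <- oracle_radii(s1); r2 <- oracle_radii(s2)
  bp <- default_layer_scheme()$breakpoints
  l1 <- oracle_shell_counts(r1, bp); l2 <- oracle_shell_counts(r2, bp)
  expect_equal(unname(v["s1"]), oracle_density(l1, l2), tolerance = 1e-12)
  expect_equal(unname(v["s2"]), 1 - abs(400 - 550) / 400, tolerance = 1e-12)
  frac <- function(s, el) sum(s$atoms$element == el) / nrow(s$atoms)
  for (i in 5:7) {
    el <- c("C", "N", "O")[i - 4]
    expect_equal(unname(v[paste0("s", i)]),
                 1 - abs(frac(s1, el) - frac(s2, el)) / frac(s1, el),
                 tolerance = 1e-12)
  }
  expect_true(v["s8"] %in% c(1.0, 0.8, 0.0))
  expect_true(v["s9"] %in% c(1.0, 0.8, 0.0))
  # identity
  expect_equal(unname(parameter_vector(s1, s1)), rep(1, 9), tolerance = 1e-12)
})

test_that("the overall similarity is a plain dot product under the packaged weights", {
  w <- table1_weights()
  expect_equal(overall_similarity(rep(1, 9), w), 1.0007, tolerance = 1e-10)
  expect_equal(overall_similarity(rep(0, 9), w), 0)
  # frozen hand arithmetic for the published S100A11 row
  t4 <- table4_fixture()
  a11 <- as.numeric(t4[t4$protein == "S100A11", paste0("s", 1:9)])
  expect_equal(overall_similarity(a11, w), 0.83284468, tolerance = 1e-8)
  # the published overall for that row differs from the dot product; both kept
  expect_equal(t4$printed_overall[t4$protein == "S100A11"], 0.8102)
  expect_error(overall_similarity(rep(1, 8), w), "nine components")
})

test_that("reference-protein ranking is deterministic and puts S100A11 first", {
  t4 <- table4_fixture()
  r <- rank_reference_proteins(t4)
  expect_equal(nrow(r), 17L)
  expect_equal(r$protein[1], "S100A11")
  expect_true(all(diff(r$score) <= 0))
  # permutation invariance
  set.seed(9)
  r2 <- rank_reference_proteins(t4[sample(nrow(t4)), ])
  expect_equal(r, r2)
  single <- rank_reference_proteins(t4[3, ])
  expect_equal(single$protein, t4$protein[3])
})
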