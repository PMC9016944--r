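# brute-force oracles kept deliberately naive
oracle_step_satisfied <- function(step, gene_set) {
  any(sapply(step$alternatives, function(req) all(req %in% gene_set)))
}
oracle_complete <- function(definition, gene_set) {
  any(sapply(enumerate_variants(definition), function(v) {
    all(sapply(v, function(req) all(req %in% gene_set)))
  }))
}

random_grammar <- function(seed) {
  set.seed(seed)
  n_steps <- sample(2:4, 1)
  steps <- lapply(seq_len(n_steps), function(k) {
    n_alt <- sample(1:3, 1)
    alts <- lapply(seq_len(n_alt), function(a) {
      sample(paste0("g", 1:8), sample(1:3, 1))
    })
    list(label = paste0("step", k), alternatives = alts)
  })
  gutsulfur:::new_pathway_definition(paste0("rand", seed), steps)
}

test_that("the shipped taurine grammars enumerate 4 variants each", {
  defs <- load_pathway_grammar(catalog = default_catalog())
  expect_named(defs, c("taurine_reduction_3step", "taurine_reduction_4step"))
  v3 <- enumerate_variants(defs$taurine_reduction_3step)
  v4 <- enumerate_variants(defs$taurine_reduction_4step)
  expect_length(v3, 4)
  expect_length(v4, 4)
  labels <- sapply(v3, function(v) paste(sapply(v, paste, collapse = "+"),
                                         collapse = "|"))
  expect_equal(labels, c("tpa|xsc|dsrA+dsrB", "tpa|xsc|asrA+asrB+asrC",
                         "toa|xsc|dsrA+dsrB", "toa|xsc|asrA+asrB+asrC"))
})

test_that("grammar validation rejects empty steps and unknown symbols", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("pathways:", "  - name: bad", "    steps:",
               "      - label: s1", "        alternatives: []",
               "      - label: s2", "        alternatives: [[tpa]]"), path)
  expect_error(load_pathway_grammar(path), "zero alternatives")

  writeLines(c("pathways:", "  - name: bad", "    steps:",
               "      - label: s1", "        alternatives: [[notagene]]",
               "      - label: s2", "        alternatives: [[tpa]]"), path)
  expect_error(load_pathway_grammar(path, catalog = default_catalog()),
               "notagene")
})

test_that("variant count equals the product of alternative counts", {
  for (seed in 1:15) {
    d <- random_grammar(seed)
    expected <- prod(sapply(d$steps, function(s) length(s$alternatives)))
    expect_length(enumerate_variants(d), expected)
  }
})

test_that("pathway calls match the published taurine examples", {
  defs <- load_pathway_grammar(catalog = default_catalog())
  d3 <- defs$taurine_reduction_3step

  pc <- call_pathway(c("tpa", "xsc", "dsrA", "dsrB"), d3)
  expect_equal(pc$status, "complete")
  expect_equal(unname(sapply(pc$variant, paste, collapse = "+")),
               c("tpa", "xsc", "dsrA+dsrB"))

  pc <- call_pathway(c("tpa", "dsrA", "dsrB"), d3)
  expect_equal(pc$status, "first_and_last_only")
  expect_equal(pc$missing_steps, "sulfoacetaldehyde cleavage")

  pc <- call_pathway(character(0), d3)
  expect_equal(pc$status, "absent")
  expect_length(pc$missing_steps, 3)

  # near_complete: exactly one missing step that is first or last
  pc <- call_pathway(c("tpa", "xsc"), d3)
  expect_equal(pc$status, "near_complete")

  # terminal reporting distinguishes dsrAB from asrABC completions
  pc <- call_pathway(c("toa", "xsc", "asrA", "asrB", "asrC"), d3)
  expect_equal(pc$terminal, "asrA+asrB+asrC")
})

test_that("call_pathway agrees with the brute-force subset oracle", {
  defs <- load_pathway_grammar(catalog = default_catalog())
  universe <- c("tpa", "toa", "xsc", "isfD", "islA", "islB",
                "dsrA", "dsrB", "asrA", "asrB", "asrC", "mgl")
  set.seed(41)
  for (i in 1:400) {
    gs <- sample(universe, rbinom(1, length(universe), 0.4))
    for (d in defs) {
      pc <- call_pathway(gs, d)
      expect_equal(pc$status == "complete", oracle_complete(d, gs))
      sat <- sapply(d$steps, oracle_step_satisfied, gene_set = gs)
      expect_equal(unname(pc$satisfied), unname(sat))
    }
  }
})

test_that("adding genes never demotes a pathway status", {
  defs <- load_pathway_grammar(catalog = default_catalog())
  rank <- c(absent = 0, first_and_last_only = 1, near_complete = 1, complete = 2)
  universe <- c("tpa", "toa", "xsc", "isfD", "islA", "islB",
                "dsrA", "dsrB", "asrA", "asrB", "asrC")
  set.seed(43)
  for (i in 1:100) {
    gs <- sample(universe, rbinom(1, length(universe), 0.3))
    extra <- sample(setdiff(universe, gs), 1)
    for (d in defs) {
      before <- call_pathway(gs, d)
      after <- call_pathway(c(gs, extra), d)
      expect_gte(rank[[after$status]], rank[[before$status]])
      expect_true(all(after$satisfied >= before$satisfied))
    }
  }
})

test_that("participant pooling detects metabolic-cooperation candidates", {
  defs <- load_pathway_grammar(catalog = default_catalog())
  genes <- c("tpa", "toa", "xsc", "dsrA", "dsrB", "asrA", "asrB", "asrC")
  counts <- matrix(0L, nrow = 3, ncol = length(genes),
                   dimnames = list(c("m1", "m2", "m3"), genes))
  counts["m1", c("tpa", "xsc")] <- 1L
  counts["m2", c("asrA", "asrB", "asrC")] <- 1L
  counts["m3", c("toa", "xsc", "dsrA", "dsrB")] <- 1L
  m <- structure(list(counts = counts), class = "presence_matrix")
  records <- data.frame(mag_id = c("m1", "m2", "m3"),
                        participant_id = c("pA", "pA", "pB"),
                        disease_state = "carcinoma",
                        genus_label = c("G1", "G2", "G3"),
                        stringsAsFactors = FALSE)
  calls <- call_pathways_at_level(m, records, defs["taurine_reduction_3step"],
                                  level = "participant")
  pa <- calls[calls$unit_id == "pA", ]
  pb <- calls[calls$unit_id == "pB", ]
  # pA: no single MAG completes, but the union does -> cooperation candidate
  expect_equal(pa$status, "complete")
  expect_true(pa$cooperation_candidate)
  # pB: one MAG already complete -> not a cooperation candidate
  expect_equal(pb$status, "complete")
  expect_false(pb$cooperation_candidate)

  # single-MAG participants: participant level equals MAG level
  solo <- data.frame(mag_id = c("m1", "m2", "m3"),
                     participant_id = c("q1", "q2", "q3"),
                     disease_state = "healthy", genus_label = "G",
                     stringsAsFactors = FALSE)
  at_mag <- call_pathways_at_level(m, solo, defs, level = "mag")
  at_part <- call_pathways_at_level(m, solo, defs, level = "participant")
  expect_equal(at_mag[order(at_mag$pathway, at_mag$unit_id),
                      c("pathway", "status", "variant", "missing_steps")],
               at_part[order(at_part$pathway, at_part$unit_id),
                       c("pathway", "status", "variant", "missing_steps")],
               ignore_attr = TRUE)
})

test_that("level pooling equals brute-force set unions on random cohorts", {
  defs <- load_pathway_grammar(catalog = default_catalog())
  cat79 <- default_catalog()
  genes <- c("tpa", "toa", "xsc", "dsrA", "dsrB", "asrA", "asrB", "asrC")
  set.seed(47)
  for (rep in 1:5) {
    n <- 10
    counts <- matrix(rbinom(n * length(genes), 1, 0.3), nrow = n,
                     dimnames = list(paste0("m", 1:n), genes))
    records <- data.frame(
      mag_id = paste0("m", 1:n),
      participant_id = sample(paste0("p", 1:4), n, replace = TRUE),
      disease_state = "healthy",
      genus_label = sample(c("GA", "GB"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    m <- structure(list(counts = counts), class = "presence_matrix")
    for (lv in c("genus", "participant")) {
      key <- if (lv == "genus") records$genus_label else records$participant_id
      calls <- call_pathways_at_level(m, records, defs, level = lv)
      for (u in unique(key)) {
        pooled <- colnames(counts)[colSums(counts[key == u, , drop = FALSE]) > 0]
        for (d in defs) {
          expect_equal(
            calls$status[calls$unit_id == u & calls$pathway == d$name],
            call_pathway(pooled, d)$status)
        }
      }
    }
  }
})

test_that("gene co-occurrence tables match a brute-force tally", {
  counts <- rbind(m1 = c(tpa = 1L, toa = 1L), m2 = c(tpa = 0L, toa = 1L),
                  m3 = c(tpa = 1L, toa = 1L), m4 = c(tpa = 0L, toa = 0L))
  m <- structure(list(counts = counts), class = "presence_matrix")
  tab <- cooccurrence_table(m, "tpa", "toa")
  expect_equal(sum(tab), 4L)
  expect_equal(tab["tpa+", "toa-"], 0L)  # every tpa MAG also carries toa
  expect_equal(tab["tpa-", "toa+"], 1L)
  expect_error(cooccurrence_table(m, "tpa", "zz"), "zz")

  # disjoint carriage: both-cell is zero
  counts2 <- rbind(m1 = c(a = 1L, b = 0L), m2 = c(a = 0L, b = 1L))
  m2 <- structure(list(counts = counts2), class = "presence_matrix")
  expect_equal(cooccurrence_table(m2, "a", "b")["a+", "b+"], 0L)

  set.seed(53)
  for (rep in 1:10) {
    counts <- matrix(rbinom(40, 2, 0.4), nrow = 10,
                     dimnames = list(paste0("m", 1:10), paste0("g", 1:4)))
    m <- structure(list(counts = counts), class = "presence_matrix")
    a <- counts[, "g1"] >= 1; b <- counts[, "g3"] >= 1
    tab <- cooccurrence_table(m, "g1", "g3")
    expect_equal(as.vector(tab),
                 c(sum(a & b), sum(!a & b), sum(a & !b), sum(!a & !b)))
    expect_equal(tab, t(cooccurrence_table(m, "g3", "g1")), ignore_attr = TRUE)
  }
})
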