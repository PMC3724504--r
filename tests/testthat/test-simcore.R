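test_that("mutate_sequence is a pure substitution process", {
  seq <- make_progenitor(400, 0.5, seed = 3)

  # zero rate is the identity
  expect_identical(mutate_sequence(seq, 0, seed = 1), seq)

  # length conserved, only ACGT, and every changed site carries a new base
  out <- mutate_sequence(seq, 20, seed = 2)
  expect_equal(nchar(out), nchar(seq))
  a <- str_chars(seq); b <- str_chars(out)
  expect_true(all(b %in% c("A", "C", "G", "T")))
  changed <- which(a != b)
  expect_true(length(changed) > 0)
  expect_true(all(a[changed] != b[changed]))

  # negative or non-finite rate is a parameter error
  expect_error(mutate_sequence(seq, -1), "non-negative")
  expect_error(mutate_sequence(seq, Inf), "finite")
})

test_that("mutation counts are Poisson with the requested mean", {
  # 500 seeded calls at expected 16 subs on 1000 nt; the per-call count is
  # Poisson(16) and sites are distinct within a call, so Hamming = count
  seq <- make_progenitor(1000, 0.5, seed = 1)
  counts <- vapply(1:500, function(s) {
    hamming(seq, mutate_sequence(seq, 16, seed = s))
  }, 0)
  se <- sqrt(16 / 500)
  expect_lt(abs(mean(counts) - 16), 3 * se)
  # Poisson: variance comparable to mean
  expect_gt(var(counts), 16 * 0.7)
  expect_lt(var(counts), 16 * 1.4)
})

test_that("birth cycles follow the scaled Beta distribution", {
  expect_identical(draw_birth_cycles(0, 2, 2, 5000), integer(0))
  expect_error(draw_birth_cycles(5, -1, 2, 5000), "positive")

  b <- draw_birth_cycles(10000, 2, 2, 5000, seed = 42)
  expect_true(!is.unsorted(b))
  expect_true(all(b >= 1 & b <= 4999))
  # Beta(2,2): mean 1/2, variance 1/20 -> 2500 and 1.25e6 on 5000 cycles
  expect_lt(abs(mean(b) - 2500), 3 * sqrt(1.25e6 / 10000))
  expect_lt(abs(var(b) / 1.25e6 - 1), 0.05)

  # Beta(1,1) = Uniform(0, n_cycles)
  u <- draw_birth_cycles(10000, 1, 1, 5000, seed = 42)
  expect_lt(abs(mean(u) - 2500), 3 * 5000 / sqrt(12 * 10000))
  expect_lt(abs(var(u) / (5000^2 / 12) - 1), 0.05)
})

test_that("zero-rate simulation returns the progenitor unchanged", {
  p <- sim_params(n_cycles = 100, progenitor_rate = 0, descendant_rate = 0,
                  n_descendants = 4, seq_length = 200, seed = 5)
  sim <- run_simulation(p)
  expect_length(sim$sequences, 5)
  expect_true(all(sim$sequences == sim$sequences[["prog"]]))
})

test_that("simulation output is reproducible and structurally sound", {
  p <- sim_params(n_cycles = 1000, n_descendants = 6, seq_length = 500,
                  seed = 99)
  sim1 <- run_simulation(p)
  sim2 <- run_simulation(p)
  expect_identical(sim1, sim2)

  # no indels: every sequence keeps the progenitor length
  expect_true(all(nchar(sim1$sequences) == 500))
  # labels encode birth cycles consistent with the event log
  desc <- sim1$lineages[sim1$lineages$label != "prog", ]
  expect_true(all(grepl("^d", desc$label)))
  expect_equal(as.integer(sub("_.*$", "", sub("^d", "", desc$label))),
               desc$birth_cycle)
  expect_true(all(desc$birth_cycle >= 1 & desc$birth_cycle <= 999))
})

test_that("prog-descendant divergence matches the rate x time expectation", {
  # one descendant per run; expected substitution events between prog and
  # descendant are (rp + rd) * (n_cycles - birth); estimate events from the
  # JC-corrected distance (which undoes multiple hits on average)
  rp <- 0.02; rd <- 0.16; L <- 1000; Tn <- 500
  obs <- exp <- numeric(150)
  for (s in seq_along(obs)) {
    sim <- run_simulation(sim_params(n_cycles = Tn, progenitor_rate = rp,
                                     descendant_rate = rd, n_descendants = 1,
                                     seq_length = L, seed = s))
    t_birth <- sim$lineages$birth_cycle[2]
    exp[s] <- (rp + rd) * (Tn - t_birth)
    obs[s] <- jc_distance(sim$sequences)[1, 2] * L
  }
  expect_lt(abs(sum(obs) / sum(exp) - 1), 0.1)
})

test_that("co-speciation produces a closely related labeled pair", {
  p <- replacement_preset("cospeciation", seed = 7)
  sim <- run_simulation(p)
  expect_length(sim$sequences, 14)  # prog + 12 descendants + 1 extra lineage
  expect_true(all(c("cospec1", "cospec2") %in% names(sim$sequences)))
  # the split lineage descends from the earliest-born descendant
  li <- sim$lineages
  expect_equal(li$parent[li$label == "cospec1"],
               li$parent[li$label == "cospec2"])
  expect_equal(li$birth_cycle[li$label == "cospec1"], 2500)

  # the shared stem seeds synapomorphies: NJ groups the cospec pair as
  # sisters in essentially every run (raw pairwise distance alone does not
  # single them out, because the slow progenitor and late-born descendants
  # sit at comparable distances; the tree separates shared from private
  # signal)
  sisters <- vapply(1:50, function(s) {
    sim <- run_simulation(replacement_preset("cospeciation", seed = s))
    tr <- nj_tree(jc_distance(sim$sequences))
    tr$node.label <- rep(1, tr$Nnode)
    !is.na(bipartition_support(tr, c("cospec1", "cospec2")))
  }, TRUE)
  expect_gte(mean(sisters), 0.95)
})

test_that("a split cycle before the lineage's birth is a configuration error", {
  p <- sim_params(n_cycles = 5000, n_descendants = 1, seq_length = 200,
                  cospec_cycle = 2, seed = 1)
  # with one descendant born at a Beta(2,2) time, cycle 2 precedes its birth
  expect_error(run_simulation(p), "not after the birth")
  expect_error(sim_params(cospec_cycle = 6000), "n_cycles")
  expect_error(sim_params(n_descendants = 0, cospec_cycle = 10),
               "at least one descendant")
})

test_that("per-site rate interpretation scales rates by sequence length", {
  # per-site 0.00001 on 500 nt == per-sequence 0.005
  s1 <- run_simulation(sim_params(n_cycles = 2000, progenitor_rate = 1e-5,
                                  descendant_rate = 8e-5, n_descendants = 2,
                                  seq_length = 500, rate_unit = "per_site",
                                  seed = 3))
  s2 <- run_simulation(sim_params(n_cycles = 2000, progenitor_rate = 5e-3,
                                  descendant_rate = 4e-2, n_descendants = 2,
                                  seq_length = 500, seed = 3))
  expect_identical(s1$sequences, s2$sequences)
})

test_that("simulation round-trips through FASTA and the event log", {
  sim <- run_simulation(sim_params(n_cycles = 300, n_descendants = 3,
                                   seq_length = 200, seed = 12))
  dir <- withr::local_tempdir()
  files <- write_simulation(sim, dir)
  expect_true(all(file.exists(files)))
  back <- read_fasta(files[["fasta"]])
  expect_identical(back[names(sim$sequences)], sim$sequences)
  log <- read.delim(files[["events"]])
  expect_identical(log$label, sim$lineages$label)
})
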