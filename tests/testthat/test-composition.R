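sch_int <- hydrolysis_scheme("intact")
sch_hcl <- hydrolysis_scheme("hcl")
sch_msa <- hydrolysis_scheme("msa")

test_that("residue counts match a brute-force tally", {
  expect_equal(residue_counts(protein_record("p", "QQQ"))[["Q"]], 3L)
  cnt <- residue_counts(protein_record("p", "QEQE"))
  expect_equal(cnt[["Q"]], 2L)
  expect_equal(cnt[["E"]], 2L)
  withr::local_seed(3)
  for (i in 1:5) {
    rec <- random_record(60)
    cnt <- residue_counts(rec)
    tal <- oracle_tally(rec$sequence)
    for (aa in names(tal)) expect_equal(cnt[[aa]], unname(tal[aa]))
    expect_equal(sum(cnt), 60L)
  }
})

test_that("hydrolysis schemes pool and destroy as their chemistry dictates", {
  expect_equal(sch_hcl$channel_map[["Q"]], "Glx")
  expect_equal(sch_hcl$channel_map[["N"]], "Asx")
  expect_equal(sch_hcl$recovery[["W"]], 0)
  expect_equal(sch_msa$recovery[["W"]], 1)
  expect_equal(unname(sch_int$channel_map[["Q"]]), "Gln")
  expect_error(hydrolysis_scheme("hcl", recovery = c(W = 1)), "fixed at 0")
  expect_error(hydrolysis_scheme("msa", recovery = c(C = 1.2)), "\\[0, 1\\]")
})

test_that("protein composition pools channels and models Trp loss", {
  expect_equal(
    protein_composition(protein_record("p", "QQQ"), sch_int)$fractions[["Gln"]],
    1.0)
  expect_equal(
    protein_composition(protein_record("p", "QQEE"), sch_hcl)$fractions[["Glx"]],
    1.0)
  wggg <- protein_record("p", "WGGG")
  expect_equal(protein_composition(wggg, sch_hcl)$fractions[["Gly"]], 1.0)
  msa <- protein_composition(wggg, sch_msa)$fractions
  expect_equal(msa[["Trp"]], 0.25)
  expect_equal(msa[["Gly"]], 0.75)
  expect_error(protein_composition(protein_record("w", "WWW"), sch_hcl),
               "no recoverable residues")
})

test_that("pooling conserves mass and hcl/msa agree off their differences", {
  withr::local_seed(21)
  for (i in 1:10) {
    rec <- random_record(sample(50:300, 1))
    intact <- protein_composition(rec, sch_int)$fractions
    msa <- protein_composition(rec, sch_msa)$fractions
    # Glx = Gln + Glu, Asx = Asn + Asp for any W-preserving chemistry
    expect_equal(msa[["Glx"]], intact[["Gln"]] + intact[["Glu"]],
                 tolerance = 1e-12)
    expect_equal(msa[["Asx"]], intact[["Asn"]] + intact[["Asp"]],
                 tolerance = 1e-12)
    # sequences without W, N, D, Q, E: hcl and msa identical
    stripped <- gsub("[WNDQE]", "", rec$sequence)
    if (nchar(stripped) > 0) {
      rec2 <- protein_record("s", stripped)
      expect_equal(protein_composition(rec2, sch_hcl)$fractions,
                   protein_composition(rec2, sch_msa)$fractions)
    }
  }
})

test_that("zeroing one residue's recovery rescales all other channels", {
  withr::local_seed(4)
  rec <- random_record(200)
  base <- protein_composition(rec, sch_msa)$fractions
  mod <- protein_composition(rec, hydrolysis_scheme("msa",
                                                    recovery = c(C = 0)))
  expect_equal(mod$fractions[["Cys"]], 0)
  other <- setdiff(names(base), "Cys")
  ratios <- mod$fractions[other] / base[other]
  ratios <- ratios[is.finite(ratios) & base[other] > 0]
  expect_true(max(ratios) - min(ratios) < 1e-12)
})

test_that("ambiguity codes feed the pooled channels they determine", {
  recs <- suppressWarnings(protein_record("amb", "BZGG"))
  comp <- protein_composition(recs, sch_hcl)
  expect_equal(comp$fractions[["Asx"]], 0.25)
  expect_equal(comp$fractions[["Glx"]], 0.25)
  expect_equal(comp$fractions[["Gly"]], 0.5)
  # X excluded from the denominator
  recx <- suppressWarnings(protein_record("x", "XGG"))
  expect_equal(protein_composition(recx, sch_int)$fractions[["Gly"]], 1.0)
  expect_equal(protein_composition(recx, sch_int)$n_residues, 2)
})

test_that("mixture composition weights residue counts by chain amounts", {
  s2 <- protein_record("s2", "SS")
  g4 <- protein_record("g4", "GGGG")
  mix <- mixture_composition(list(s2, g4), c(1, 1), sch_int, "molar_chain")
  expect_equal(mix$fractions[["Ser"]], 2 / 6)
  expect_equal(mix$fractions[["Gly"]], 4 / 6)

  # all weight on one component = that component's composition
  withr::local_seed(9)
  a <- random_record(80, "a"); b <- random_record(120, "b")
  for (mode in c("molar_chain", "mass")) {
    solo <- mixture_composition(list(a, b), c(1, 0), sch_msa, mode)
    expect_equal(solo$fractions, protein_composition(a, sch_msa)$fractions)
  }

  # equal-length, equal-molar mixture = arithmetic mean of compositions
  c1 <- random_record(100, "c1"); c2 <- random_record(100, "c2")
  mix2 <- mixture_composition(list(c1, c2), c(1, 1), sch_int, "molar_chain")
  mean_fr <- (protein_composition(c1, sch_int)$fractions +
              protein_composition(c2, sch_int)$fractions) / 2
  expect_equal(mix2$fractions, mean_fr, tolerance = 1e-12)

  # molar and mass modes agree when chain masses are equal
  d1 <- protein_record("d1", "GGGG"); d2 <- protein_record("d2", "GGGG")
  e1 <- protein_record("e1", strrep("GA", 10))
  e2 <- protein_record("e2", strrep("AG", 10))
  expect_equal(
    mixture_composition(list(e1, e2), c(2, 3), sch_int, "molar_chain")$fractions,
    mixture_composition(list(e1, e2), c(2, 3), sch_int, "mass")$fractions,
    tolerance = 1e-9)

  expect_error(mixture_composition(list(), numeric(0), sch_int), "empty")
  expect_error(mixture_composition(list(a, b), c(0, 0), sch_int),
               "not all zero")
})

test_that("molecular weights derive from elemental composition", {
  expect_equal(molecular_weight("E", "free"), 147.13, tolerance = 0.005)
  # glycylglycine chain mass against an explicit elemental-formula sum:
  # C4 H8 N2 O3
  gg_formula <- 4 * 12.011 + 8 * 1.008 + 2 * 14.007 + 3 * 15.999
  expect_equal(molecular_weight("GG", "chain"), gg_formula,
               tolerance = 1e-9)
  expect_error(molecular_weight("B", "free"), "no defined mass")
  expect_error(molecular_weight("QQ", "free"), "single residue")
  # chain mass of Q/E differs by ~1 g/mol: basis of the mass/mole interchange
  dq <- molecular_weight("E", "free") - molecular_weight("Q", "free")
  expect_lt(abs(dq - 1), 0.05)
})

test_that("polyglutamine construct edits only the tract", {
  c190 <- construct_nhtt_egfp(190)
  c21 <- construct_nhtt_egfp(21)
  expect_equal(nchar(c190$sequence) - nchar(c21$sequence), 169)
  runs <- gregexpr("Q+", c190$sequence)[[1]]
  expect_equal(max(attr(runs, "match.length")), 190)
  # non-tract sequence identical between lengths
  expect_equal(gsub("Q{21,}", "", c190$sequence),
               gsub("Q{21,}", "", c21$sequence))
  expect_error(construct_nhtt_egfp(0), "positive")
  # packaged fixture is the 190Q variant verbatim
  fx <- read_fasta(system.file("extdata", "nhtt_egfp_190q.fasta",
                               package = "depositcomp"))
  expect_equal(fx[[1]]$sequence, c190$sequence)
})

test_that("expanded tract raises the pooled Glx fraction ~2.7-fold", {
  g <- function(n)
    protein_composition(construct_nhtt_egfp(n), sch_hcl)$fractions[["Glx"]]
  expect_equal(g(190) / g(21), 2.7, tolerance = 0.15 / 2.7)
})
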