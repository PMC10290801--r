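test_that("formula parsing handles multipliers, omitted counts and bad input", {
  expect_equal(unclass(parse_formula("C25H38O6"))[c("C", "H", "O")],
               c(C = 25L, H = 38L, O = 6L))
  expect_equal(unclass(parse_formula("H2O"))[c("H", "O")], c(H = 2L, O = 1L))
  expect_equal(unclass(parse_formula("C25H39O6"))[["H"]], 39L)
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C10X2"), "unknown element")
  expect_error(parse_formula("C0H2"), "positive")
})

test_that("formatting then parsing is the identity on Hill strings", {
  for (s in c("C25H38O6", "H2O", "C6H12O6", "CH4", "C2H6OS", "NO2", "HNO3"))
    expect_identical(format_formula(parse_formula(s)), s)
})

test_that("monoisotopic mass reproduces tabulated reference values", {
  # 12C defines the unified mass scale
  expect_identical(monoisotopic_mass(parse_formula("C"), 0), 12)
  # frozen sums over NIST monoisotopic masses (independent hand calculation)
  expect_equal(monoisotopic_mass("C25H38O6", 0), 434.26684, tolerance = 5e-4)
  expect_equal(monoisotopic_mass("H2O", 0), 18.0105646, tolerance = 1e-6)
  # protonated rasfonin ion, electron-corrected
  expect_equal(monoisotopic_mass("C25H39O6", charge = 1), 435.2741,
               tolerance = 5e-4)
  expect_error(monoisotopic_mass(structure(c(Zz = 1L), class = "molecular_formula")),
               "no monoisotopic mass")
})

test_that("mass is additive over disjoint formulas and monotone in counts", {
  a <- parse_formula("C6H12")
  b <- parse_formula("N2O3")
  ab <- parse_formula("C6H12N2O3")
  expect_equal(monoisotopic_mass(ab), monoisotopic_mass(a) + monoisotopic_mass(b))
  for (el in c("C", "H", "O")) {
    plus <- unclass(parse_formula("C25H38O6"))
    plus[el] <- plus[el] + 1L
    expect_gt(monoisotopic_mass(structure(plus, class = "molecular_formula")),
              monoisotopic_mass("C25H38O6"))
  }
})

test_that("module tailoring maps beta states to reductive domain demands", {
  expect_setequal(module_tailoring("hydroxyl", FALSE), "KR")
  expect_setequal(module_tailoring("enoyl", TRUE), c("KR", "DH", "MT"))
  expect_setequal(module_tailoring("reduced", FALSE), c("KR", "DH", "ER"))
  expect_setequal(module_tailoring("ketone", FALSE), character(0))
  expect_error(module_tailoring("starter"), "starter")
})

test_that("chain decomposition counts units, extensions and methyls", {
  ras <- rasfonin_compound()
  hexa <- decompose_chain(ras$chains[[1]])
  tetra <- decompose_chain(ras$chains[[2]])
  expect_equal(hexa$units, 6L)
  expect_equal(hexa$extensions, 5L)
  expect_equal(hexa$methyls, 3L)
  expect_equal(tetra$units, 4L)
  expect_equal(tetra$extensions, 3L)
  expect_equal(tetra$methyls, 2L)
  expect_setequal(required_domains(hexa), c("KS", "AT", "DH", "MT", "ER", "KR", "ACP"))
  expect_setequal(required_domains(tetra), c("KS", "AT", "DH", "MT", "ER", "KR", "ACP"))

  solo <- chain_spec("starter_only", list(ketide_unit(1, FALSE, "starter")),
                     release = "hydrolysis")
  req <- decompose_chain(solo)
  expect_equal(req$units, 1L)
  expect_equal(req$extensions, 0L)
  expect_setequal(required_domains(req), c("KS", "AT", "ACP"))
})

test_that("extensions = units - 1 holds for random chain specs", {
  set.seed(11)
  for (i in 1:50) {
    spec <- random_chain(sample(1:12, 1))
    req <- decompose_chain(spec)
    expect_equal(req$extensions, req$units - 1L)
    expect_true(all(c("KS", "AT", "ACP") %in% required_domains(req)))
  }
})

test_that("required domains grow monotonically with methylation and reduction depth", {
  depth <- c("ketone", "hydroxyl", "enoyl", "reduced")
  base <- chain_spec("b", list(ketide_unit(1, FALSE, "starter"),
                               ketide_unit(2, FALSE, "ketone")))
  prev <- required_domains(decompose_chain(base))
  for (st in depth[-1]) {
    cur <- required_domains(decompose_chain(
      chain_spec("b", list(ketide_unit(1, FALSE, "starter"),
                           ketide_unit(2, FALSE, st)))))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  with_mt <- required_domains(decompose_chain(
    chain_spec("b", list(ketide_unit(1, FALSE, "starter"),
                         ketide_unit(2, TRUE, "reduced")))))
  expect_true(all(prev %in% with_mt) && "MT" %in% with_mt)
})

test_that("compound carbon bookkeeping accepts rasfonin and rejects mismatches", {
  ras <- rasfonin_compound()
  # 2*(6+4) backbone carbons + 5 methyls = 25 = C count of C25H38O6
  expect_equal(unclass(ras$formula)[["C"]], 25L)
  expect_error(
    compound_spec("bad", ras$chains, formula = "C24H38O6"),
    "carbon bookkeeping")
})

test_that("retro report derives post-assembly enzyme demands", {
  rep_ras <- retro_compound(rasfonin_compound())
  expect_true("O_acyltransferase" %in% names(rep_ras$post_pks_enzymes))
  expect_true("trans_thioesterase" %in% names(rep_ras$post_pks_enzymes))
  expect_equal(rep_ras$post_pks_enzymes[["cytochrome_p450"]], 3L)

  solo <- compound_spec(
    "mono",
    list(chain_spec("c", list(ketide_unit(1, FALSE, "starter"),
                              ketide_unit(2, FALSE, "ketone")),
                    release = "hydrolysis")),
    formula = "C4H6O3")
  rep_solo <- retro_compound(solo)
  expect_false("O_acyltransferase" %in% names(rep_solo$post_pks_enzymes))
  expect_true("trans_thioesterase" %in% names(rep_solo$post_pks_enzymes))
})

test_that("compound YAML round-trips through read_compound_spec", {
  path <- system.file("extdata", "rasfonin.yaml", package = "retrobgc")
  expect_true(nzchar(path))
  from_yaml <- read_compound_spec(path)
  built <- rasfonin_compound()
  expect_equal(from_yaml$name, built$name)
  expect_equal(format_formula(from_yaml$formula), format_formula(built$formula))
  for (i in 1:2) {
    expect_equal(decompose_chain(from_yaml$chains[[i]]),
                 decompose_chain(built$chains[[i]]))
  }
  expect_equal(retro_compound(from_yaml)$post_pks_enzymes,
               retro_compound(built)$post_pks_enzymes)
})
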