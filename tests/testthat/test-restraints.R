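# Restraint construction, weighting, rendering and parsing.

test_that("eligible steps yield 22 class-targeted records each", {
  s <- fx_duplexA(); lib <- fx_lib(); a <- fx_assignA()
  rs <- build_restraints(a, lib, s)
  expect_equal(nrow(rs$records), 34 * 22)
  one <- rs$records[rs$records$step_label == "A.DG1_DG2", ]
  expect_equal(nrow(one), 22)
  expect_setequal(one$parameter, ntckit:::TORSION_PARAMS)
  # targets equal the class targets, not the model's own torsions
  tgt <- lib$classes$AA00$targets
  expect_equal(one$target[match(names(tgt[ntckit:::TORSION_PARAMS]),
                                one$parameter)],
               unname(tgt[ntckit:::TORSION_PARAMS]), tolerance = 1e-9)
  # distances carry no period, torsions period 1
  expect_true(all(is.na(one$period[one$parameter %in% c("d_nn", "d_cc")])))
  expect_true(all(one$period[!one$parameter %in% c("d_nn", "d_cc")] == 1))
})

test_that("targets stay at class values even when the model deviates", {
  lib <- fx_lib()
  set.seed(9)
  spec <- fixture_spec(sequence = "GGTACC", torsion_noise_sigma = 4, seed = 9)
  s <- build_duplex(spec)
  a <- assign_structure(s, lib)
  el <- a[a$eligible, ]
  expect_gt(nrow(el), 0)
  rs <- build_restraints(a, lib, s)
  steps <- attr(a, "steps")
  model_dev <- numeric()
  for (i in seq_len(min(3, nrow(el)))) {
    st <- steps[steps$label == el$step_label[i], ]
    tv <- step_torsions(s, st)
    recs <- rs$records[rs$records$step_label == el$step_label[i], ]
    tgt <- lib$classes[[el$ntc[i]]]$targets
    d1 <- recs$target[recs$parameter == "epsilon1"]
    expect_equal(d1, unname(tgt["epsilon1"]), tolerance = 1e-9)
    model_dev <- c(model_dev, abs(circ_diff(tv[["epsilon1"]], tgt[["epsilon1"]])))
  }
  # the noisy model's own torsions do differ from the class targets, so the
  # equality above proves restraints do not chase the model
  expect_gt(max(model_dev), 0.1)
})

test_that("the eligibility gate and step selection filter records", {
  s <- fx_duplexA(); lib <- fx_lib(); a <- fx_assignA()
  # no record for any ineligible step (force ineligibility artificially)
  a2 <- a; a2$eligible <- FALSE
  attr(a2, "steps") <- attr(a, "steps")
  rs0 <- build_restraints(a2, lib, s)
  expect_equal(nrow(rs0$records), 0)
  txt <- render_restraints(rs0, "phenix_style")
  expect_match(txt, "^# NtC restraints")
  expect_equal(length(strsplit(txt, "\n")[[1]]), 1)  # header-only
  # residue selection 1-7,12-18 leaves 8-11 unrestrained
  sel <- parse_step_selection("1-7,12-18")
  expect_equal(sel, c(1:7, 12:18))
  rs <- build_restraints(a, lib, s, include_residues = sel)
  touched <- sort(unique(c(rs$records$resno1, rs$records$resno2)))
  expect_true(all(!(8:11 %in% touched)))
  expect_equal(length(unique(rs$records$step_label)), 2 * (6 + 6))
})

test_that("weights tighten sigmas monotonically and clamps apply", {
  s <- fx_duplexA(); lib <- fx_lib(); a <- fx_assignA()
  rs1 <- build_restraints(a, lib, s, global_weight = 1)
  rs2 <- build_restraints(a, lib, s, global_weight = 2)
  expect_equal(rs2$records$sigma, rs1$records$sigma / 2, tolerance = 1e-12)
  # per-step weight tightens only that step
  w <- c("A.DG1_DG2" = 4)
  rs3 <- build_restraints(a, lib, s, per_step_weights = w)
  in_step <- rs3$records$step_label == "A.DG1_DG2"
  expect_equal(rs3$records$sigma[in_step], rs1$records$sigma[in_step] / 4)
  expect_equal(rs3$records$sigma[!in_step], rs1$records$sigma[!in_step])
  # tighter preset halves sigmas
  rs4 <- build_restraints(a, lib, s, tighter = TRUE)
  expect_equal(rs4$records$sigma, rs1$records$sigma / 2, tolerance = 1e-12)
  # clamp: torsion sigmas within [8, 25] / weight at weight 1
  tors <- !(rs1$records$parameter %in% c("d_nn", "d_cc"))
  expect_true(all(rs1$records$sigma[tors] >= 8 & rs1$records$sigma[tors] <= 25))
  dist <- !tors
  expect_true(all(rs1$records$sigma[dist] >= 0.05 & rs1$records$sigma[dist] <= 0.3))
  expect_error(build_restraints(a, lib, s, global_weight = 0), "positive")
})

test_that("both dialects render deterministically and parse back", {
  s <- fx_duplexA(); lib <- fx_lib(); a <- fx_assignA()
  rs <- build_restraints(a, lib, s,
                         include_residues = parse_step_selection("1-3"))
  for (d in c("phenix_style", "refmac_style")) {
    t1 <- render_restraints(rs, d)
    t2 <- render_restraints(rs, d)
    expect_identical(t1, t2)
    pb <- parse_restraints(t1, d)
    expect_equal(nrow(pb$records), nrow(rs$records))
    expect_equal(pb$records$parameter, rs$records$parameter)
    expect_equal(pb$records$target, rs$records$target, tolerance = 1e-6)
    expect_equal(pb$records$sigma, rs$records$sigma, tolerance = 1e-6)
    expect_equal(pb$records$atoms, rs$records$atoms)
    expect_equal(pb$library_version, lib$version)
  }
  # dialect equivalence: identical parameter/target/sigma content
  pa <- parse_restraints(render_restraints(rs, "phenix_style"), "phenix_style")
  pr <- parse_restraints(render_restraints(rs, "refmac_style"), "refmac_style")
  expect_equal(pa$records[, c("parameter", "target", "sigma")],
               pr$records[, c("parameter", "target", "sigma")],
               tolerance = 1e-6)
  expect_error(render_restraints(rs, "buster_style"))
})

test_that("parser reports malformed lines and passes unknown lines through", {
  s <- fx_small_duplexA(); lib <- fx_lib()
  a <- assign_structure(s, lib)
  rs <- build_restraints(a, lib, s,
                         include_residues = parse_step_selection("1-2"))
  txt <- strsplit(render_restraints(rs, "refmac_style"), "\n")[[1]]
  bad <- sub("sigma [0-9.]+", "sigma twelve", txt[2])
  expect_error(parse_restraints(c(txt[1], bad), "refmac_style"),
               "line 2.*sigma|malformed sigma")
  extra <- c(txt[1], "refinement_cycles 10", txt[-1], "weight_scheme auto")
  pb <- parse_restraints(extra, "refmac_style")
  expect_equal(nrow(pb$records), nrow(rs$records))
  expect_setequal(attr(pb, "passthrough"),
                  c("refinement_cycles 10", "weight_scheme auto"))
})
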