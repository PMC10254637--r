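# scan-shaped data frame for advisor tests
fake_scan <- function(resid, resname, ddE, chain = "A") {
  data.frame(chain = chain, resid = as.integer(resid), resname = resname,
             ddE = ddE,
             effect_class = ifelse(ddE < -1, "anticatalytic",
                                   ifelse(ddE > 1, "procatalytic",
                                          "neutral")),
             stringsAsFactors = FALSE)
}

test_that("charge-cancelling substitutions follow the standard mapping", {
  expect_identical(suggest_mutation("GLU"), "GLN")
  expect_identical(suggest_mutation("ASP"), "ASN")
  expect_identical(suggest_mutation("LYS"), "GLN")
  # Arg has no conventional neutral partner: configured fallback
  expect_identical(suggest_mutation("ARG"), "GLN")
  expect_identical(suggest_mutation("SER"), "none")
  expect_error(suggest_mutation("XYZ"), "unknown")
  custom <- advisor_config(mutation_map = c(ARG = "MET"))
  expect_identical(suggest_mutation("ARG", custom), "MET")
})

test_that("exposure counts heavy neighbors of other residues", {
  # isolated charged residue: zero neighbors, exposed
  iso <- tiny_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)), c(1, 0),
                        resid = c(10L, 10L), resname = "LYS",
                        atom_name = c("NZ", "CB"))
  r <- is_exposed(iso, "A:10:LYS")
  expect_true(r$exposed)
  expect_identical(r$n_neighbors, 0L)

  # caged residue: 30 neighbors within 8 A -> buried under the default 16
  set.seed(2)
  cage <- t(vapply(1:30, function(i) 4 * {
    u <- rnorm(3); u / sqrt(sum(u^2))
  }, numeric(3)))
  s <- tiny_structure(rbind(c(0, 0, 0), c(1.5, 0, 0), cage),
                      c(1, 0, rep(0, 30)),
                      resid = c(10L, 10L, rep(99L, 30)),
                      resname = c("LYS", "LYS", rep("ALA", 30)),
                      atom_name = c("NZ", "CB", paste0("C", 1:30)))
  r <- is_exposed(s, "A:10:LYS")
  expect_false(r$exposed)
  expect_identical(r$n_neighbors, 30L)
  # permissive override flips the call
  r2 <- is_exposed(s, "A:10:LYS",
                   advisor_config(max_heavy_neighbors = 40))
  expect_true(r2$exposed)
})

test_that("toy preset plants an exposed surface set and a buried control", {
  fx <- make_toy_enzyme(toy_ncs_spec(seed = 42L))
  s <- fx$pair$reactant
  for (key in c("A:64:ASP", "A:105:ARG", "A:117:GLU")) {
    expect_true(is_exposed(s, key)$exposed, info = key)
  }
  buried <- is_exposed(s, "A:200:LYS")
  expect_false(buried$exposed)
  expect_gt(buried$n_neighbors, 16L)
})

test_that("hydrogen-bond freedom detects nearby polar heavy atoms", {
  s <- tiny_structure(rbind(c(0, 0, 0), c(3.0, 0, 0), c(20, 0, 0)),
                      c(-1, 0, 0), resid = c(1L, 2L, 3L),
                      resname = c("ASP", "SER", "ALA"),
                      atom_name = c("OD1", "OG", "CB"))
  r <- is_hbond_free(s, "A:1:ASP")
  expect_false(r$hbond_free)  # OG at 3.0 A < 3.5 cutoff
  expect_identical(r$n_contacts, 1L)
  far <- is_hbond_free(s, "A:1:ASP", advisor_config(hbond_cutoff = 2.5))
  expect_true(far$hbond_free)
})

test_that("candidacy requires strict threshold, charged type, and no exclusion", {
  xyz <- rbind(c(10, 0, 0), c(11.5, 0, 0), c(-10, 0, 0), c(-11.5, 0, 0),
               c(0, 10, 0), c(0, 11.5, 0), c(0, -10, 0), c(0, -11.5, 0))
  s <- tiny_structure(xyz, c(-1, 0, 1, 0, -1, 0, -0.4, 0.4),
                      resid = c(64L, 64L, 110L, 110L, 140L, 140L, 60L, 60L),
                      resname = c("ASP", "ASP", "LYS", "LYS", "ASP", "ASP",
                                  "TYR", "TYR"),
                      atom_name = c("OD1", "CB", "NZ", "CB", "OD1", "CB",
                                    "OH", "CZ"))
  scan <- fake_scan(c(64, 110, 140, 60), c("ASP", "LYS", "ASP", "TYR"),
                    c(-2.4, -1.0, -3.0, -2.1))
  cfg <- advisor_config(excluded_residues = "A:140:ASP")
  rep <- build_report(scan, s, cfg)
  # 64: candidate; 110: exactly -1.0, strict -> excluded; 140: on exclusion
  # list; 60: neutral type
  expect_identical(rep$candidates$resid, 64L)
  expect_identical(rep$candidates$suggested_mutation, "ASN")
  expect_setequal(rep$ineligible$resid, c(140L, 60L))
  expect_match(rep$ineligible$excluded_reason[rep$ineligible$resid == 140],
               "exclusion")
  expect_match(rep$ineligible$excluded_reason[rep$ineligible$resid == 60],
               "charged")
})

test_that("shrinking the threshold only adds candidates", {
  fx <- make_toy_enzyme(toy_ncs_spec(seed = 42L))
  scan <- deletion_scan(fx$pair, eligible = fx$truth$key)
  sets <- lapply(c(6, 4, 2, 1, 0.5, 0.05), function(th) {
    rep <- build_report(scan, fx$pair$reactant,
                        advisor_config(threshold = th))
    paste(rep$candidates$chain, rep$candidates$resid)
  })
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
})

test_that("reports are deterministic and carry a config hash", {
  fx <- make_toy_enzyme(toy_ncs_spec(seed = 42L))
  scan <- deletion_scan(fx$pair, eligible = fx$truth$key)
  r1 <- build_report(scan, fx$pair$reactant)
  r2 <- build_report(scan, fx$pair$reactant)
  expect_identical(r1$candidates, r2$candidates)
  expect_identical(r1$provenance$config_hash, r2$provenance$config_hash)
  expect_false(r1$provenance$config_hash ==
                 build_report(scan, fx$pair$reactant,
                              advisor_config(threshold = 2))$provenance$config_hash)
  # candidates never violate any individual filter
  for (i in seq_len(nrow(r1$candidates))) {
    row <- r1$candidates[i, ]
    expect_lt(row$ddE, -1.0)
    expect_true(row$resname %in% c("ASP", "GLU", "LYS", "ARG", "HIS"))
  }
  # candidates are a subset of the scan
  expect_true(all(r1$candidates$resid %in% scan$resid))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(r1, f)
  tsv <- read.delim(f)
  expect_setequal(tsv$section, c("candidate", "ineligible"))
})

test_that("config JSON round trip", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(threshold = 2.5,
                            excluded_residues = c("A:109:GLU"),
                            mutation_map = list(GLU = "GLN", ASP = "ASN",
                                                LYS = "GLN", ARG = "GLN",
                                                HIS = "GLN")),
                       f, auto_unbox = TRUE)
  cfg <- read_advisor_config(f)
  expect_equal(cfg$threshold, 2.5)
  expect_identical(cfg$excluded_residues, "A:109:GLU")
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(thresold = 1), bad, auto_unbox = TRUE)
  expect_error(read_advisor_config(bad), "unknown")
})
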