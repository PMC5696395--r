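test_that("parse_fa_name understands the FA grammar and biomarker classes", {
  d <- parse_fa_name(c("16:0", "18:2ω6,9", "cy17:0", "2-OH 10:0",
                       "a15:0", "20:5w3", "14:1"))
  expect_equal(d$carbons, c(16L, 18L, 17L, 10L, 15L, 20L, 14L))
  expect_equal(d$double_bonds, c(0L, 2L, 0L, 0L, 0L, 5L, 1L))
  expect_equal(d$prefix,
               c("none", "none", "cyclo", "2-OH", "anteiso", "none", "none"))
  expect_equal(d$saturation_class,
               c("SFA", "PUFA", "SFA", "SFA", "SFA", "PUFA", "MUFA"))
  expect_equal(d$biomarker_class,
               c("none", "fungal_relative", "bacterial", "none",
                 "bacterial", "none", "none"))
  expect_equal(d$canonical[2], "18:2w6,9")
  expect_equal(d$omega_positions[[2]], c(6L, 9L))
  expect_error(parse_fa_name("not-a-fa"), "not-a-fa")
})

test_that("parsing the canonical name is a fixpoint", {
  names <- c("16:0", "18:2ω6,9", "cy17:0", "2-OH 10:0", "i16:0",
             "22:1w9")
  d1 <- parse_fa_name(names)
  d2 <- parse_fa_name(d1$canonical)
  expect_equal(d2$canonical, d1$canonical)
  expect_equal(d2[setdiff(names(d2), "raw_name")],
               d1[setdiff(names(d1), "raw_name")])
})

test_that("filter_rare applies occurrence and abundance rules together", {
  tbl <- toy_fa_table()
  out <- filter_rare(tbl, min_pct = 1, min_occurrence = 2)
  kept <- fa_columns(out)
  # 20:5w3 present in one measurement at 5%: occurrence rule
  expect_false("20:5w3" %in% kept)
  # 17:0 present everywhere at 0.4%: abundance rule
  expect_false("17:0" %in% kept)
  expect_setequal(kept, c("16:0", "18:1w9", "18:2w6,9"))
  log <- dropped_fas(out)
  expect_setequal(log$fa, c("20:5w3", "17:0"))
  # 20:5w3 also has mean 0.5% < 1, so both rules flag it
  expect_equal(unname(log$reason[log$fa == "20:5w3"]),
               "occurrence+abundance")
  expect_equal(unname(log$reason[log$fa == "17:0"]), "abundance")
  expect_error(filter_rare(tbl[0, ]), "empty")
})

test_that("planted rare FAs are exactly the ones dropped", {
  set.seed(11)
  n <- 12
  common <- matrix(runif(n * 17, 2, 12), n, 17,
                   dimnames = list(NULL, sprintf("%d:0", 4 + seq_len(17))))
  tbl <- tibble::as_tibble(common) |>
    dplyr::mutate(sample_id = paste0("m", 1:n), species = "sp", site = "s",
                  habitat = "h",
                  rare1 = c(8, rep(0, n - 1)),       # single measurement
                  rare2 = rep(0.2, n),               # mean < 1%
                  rare3 = c(0.9, 0.8, rep(0, n - 2)))  # two hits, mean < 1%
  out <- filter_rare(tbl)
  expect_setequal(dropped_fas(out)$fa, c("rare1", "rare2", "rare3"))
  expect_equal(length(fa_columns(out)), 17)
})

test_that("renormalize scales rows to 100 and is idempotent", {
  tbl <- tibble::tibble(sample_id = c("a", "b"), species = "sp", site = "s",
                        habitat = "h", f1 = c(40, 25), f2 = c(40, 75))
  out <- renormalize(tbl)
  expect_equal(out$f1, c(50, 25))
  expect_identical(renormalize(out)[c("f1", "f2")], out[c("f1", "f2")])

  set.seed(4)
  big <- tibble::as_tibble(matrix(runif(60), 6, 10,
                                  dimnames = list(NULL, paste0("f", 1:10))))
  big$sample_id <- paste0("m", 1:6); big$species <- "sp"
  big$site <- "s"; big$habitat <- "h"
  rn <- renormalize(big)
  expect_equal(rowSums(as.matrix(rn[paste0("f", 1:10)])),
               rep(100, 6), tolerance = 1e-9)

  bad <- tbl; bad$f1[1] <- 0; bad$f2[1] <- 0
  expect_error(renormalize(bad), "a")
})

test_that("logit transform matches closed forms and inverts when interior", {
  expect_equal(logit_transform(0.5), 0)
  expect_equal(logit_transform(c(0, 0.5), eps = 0.025)[1],
               log(0.025 / 0.975), tolerance = 1e-12)
  expect_equal(logit_transform(c(0.2, 0.8)), c(-log(4), log(4)),
               tolerance = 1e-12)
  expect_error(logit_transform(c(0.2, 1.3)), "0, 1")

  p <- seq(0.01, 0.99, by = 0.01)
  y <- logit_transform(p)
  expect_true(all(diff(y) > 0))
  expect_equal(1 / (1 + exp(-y)), p, tolerance = 1e-12)

  # boundary remap engages for the whole column, and only then
  with0 <- logit_transform(c(0, 0.6), eps = 0.025)
  expect_equal(with0[2], log(0.595 / 0.405), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(with0[2], log(0.6 / 0.4))))
})

test_that("species_stats pools measurements irrespective of site/habitat", {
  tbl <- tibble::tibble(
    sample_id = paste0("m", 1:3),
    species = c("one", "one", "solo"),
    site = c("s1", "s2", "s1"), habitat = c("h1", "h2", "h1"),
    f1 = c(1, 3, 7))
  st <- suppressMessages(species_stats(tbl, "f1"))
  expect_equal(st$mean[st$species == "one"], 2)
  expect_equal(st$se[st$species == "one"], 1)
  expect_equal(st$n_obs[st$species == "one"], 2)
  expect_equal(st$mean[st$species == "solo"], 7)
  expect_equal(st$se[st$species == "solo"], 0)
  expect_message(species_stats(tbl, "f1"), "solo")

  # matches direct recomputation on a generated fixture
  set.seed(9)
  big <- tibble::tibble(sample_id = paste0("m", 1:30),
                        species = rep(paste0("sp", 1:6), each = 5),
                        site = "s", habitat = "h", f = rnorm(30))
  st <- species_stats(big, "f")
  for (sp in unique(big$species)) {
    v <- big$f[big$species == sp]
    expect_equal(st$mean[st$species == sp], mean(v))
    expect_equal(st$se[st$species == sp], sd(v) / sqrt(5))
  }
})

test_that("compute_indices evaluates the index formulas", {
  row1 <- tibble::tibble(sample_id = "a", species = "sp", site = "s",
                         habitat = "h",
                         `18:1w9` = 50, `18:2w6,9` = 25, `16:0` = 25)
  i1 <- compute_indices(row1)
  expect_equal(i1$pf_ratio, 2)
  expect_equal(i1$ui, 0.5 * 1 + 0.25 * 2)
  expect_equal(i1$us_ratio, 3)
  expect_equal(i1$c20pufa_sum, 0)
  expect_equal(i1$fa_number, 3)
  expect_equal(i1$sfa_sum + i1$mufa_sum + i1$pufa_sum, 100, tolerance = 1e-9)

  row2 <- tibble::tibble(sample_id = "b", species = "sp", site = "s",
                         habitat = "h", `16:0` = 100, `18:1w9` = 0)
  i2 <- compute_indices(row2)
  expect_equal(i2$ui, 0)
  expect_equal(i2$us_ratio, 0)
  expect_true(is.na(i2$pf_ratio) && is.na(i2$bf_ratio) && is.na(i2$bp_ratio))

  row3 <- tibble::tibble(sample_id = "c", species = "sp", site = "s",
                         habitat = "h",
                         `20:4w6` = 10, `20:5w3` = 10, `16:0` = 80)
  i3 <- compute_indices(row3)
  expect_equal(i3$c20pufa_sum, 20)
  expect_equal(i3$ui, 0.1 * 4 + 0.1 * 5)

  bact <- tibble::tibble(sample_id = "d", species = "sp", site = "s",
                         habitat = "h",
                         `a15:0` = 10, `18:1w7` = 10, `18:2w6,9` = 20,
                         `18:1w9` = 30, `16:0` = 30)
  ib <- compute_indices(bact)
  expect_equal(ib$bacterial_sum, 20)
  expect_equal(ib$bf_ratio, 1)
  expect_equal(ib$bp_ratio, 2 / 3)
})

test_that("class sums partition any renormalized composition", {
  set.seed(21)
  fas <- c("16:0", "18:1w9", "18:2w6,9", "20:5w3", "cy17:0", "14:1")
  X <- matrix(runif(5 * 6), 5, 6, dimnames = list(NULL, fas))
  tbl <- tibble::as_tibble(X)
  tbl$sample_id <- paste0("m", 1:5); tbl$species <- "sp"
  tbl$site <- "s"; tbl$habitat <- "h"
  idx <- compute_indices(renormalize(tbl))
  expect_equal(idx$sfa_sum + idx$mufa_sum + idx$pufa_sum, rep(100, 5),
               tolerance = 1e-9)
})

test_that("merge_literature restricts, imputes zeros, and counts data points", {
  own <- tibble::tibble(
    sample_id = paste0("m", 1:4),
    species = c("sp one", "sp one", "sp one", "sp two"),
    site = c("s1", "s1", "s2", "s1"), habitat = "forest",
    `16:0` = c(30, 34, 40, 50), `18:1w9` = c(40, 36, 30, 20),
    `18:2w6,9` = c(20, 20, 20, 20), `20:5w3` = c(10, 10, 10, 10),
    `14:0` = c(0, 0, 0, 0))
  lit1 <- tibble::tibble(species = "sp two", site = "lit-site",
                         `16:0` = 55, `18:1w9` = 25, `18:2w6,9` = 20)
  lit2 <- tibble::tibble(species = "sp three", site = "lit-site",
                         `16:0` = 60, `18:1w9` = 40, `16:1ω5` = 0.2)
  out <- suppressWarnings(
    merge_literature(own, list(lit1, lit2),
                     tree_tips = c("sp one", "sp two")))
  # own rows averaged per species x site x habitat: sp one has 2 contexts
  expect_equal(sum(out$species == "sp one"), 2)
  # two sources, same species, different contexts -> separate data points
  expect_equal(sum(out$species == "sp two"), 2)
  # imputed-missing column present as zeros before filtering: 20:5w3 absent
  # from lit sources but kept (mean over 6 points > 1%)
  expect_true("20:5w3" %in% fa_columns(out))
  expect_equal(out$`20:5w3`[out$species == "sp three"], 0)
  # non-subset FA (14:0 is neither biomarker, C20 unsaturated, 16:0 nor
  # 18:0) removed by the subset rule even before rarity kicks in
  expect_false("14:0" %in% fa_columns(out))
  # rows renormalized
  expect_equal(rowSums(as.matrix(out[fa_columns(out)])),
               rep(100, nrow(out)), tolerance = 1e-9)
  # unmatched species flagged
  expect_equal(attr(out, "excluded_species"), "sp three")
  expect_warning(merge_literature(own, list(lit1, lit2),
                                  tree_tips = c("sp one", "sp two")),
                 "sp three")
})

test_that("combined_fa_subset keeps biomarkers, C20 unsaturated, 16:0, 18:0", {
  keep <- combined_fa_subset(c("16:0", "18:0", "14:0", "20:1w9", "20:5w3",
                               "a15:0", "18:2w6,9", "23:0", "20:0"))
  expect_equal(keep, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
                       FALSE))
})
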