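toy_pair_table <- function(sample = "s1", group = NULL) {
  df <- data.frame(class = "PE",
                   carbons = c(28L, 28L, 34L, 34L),
                   double_bonds = c(0L, 1L, 1L, 2L),
                   label = "unlabeled", sample = sample,
                   intensity = c(10, 30, 20, 20),
                   stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- group
  df
}

test_that("TLC fractions normalize each lane to 1", {
  expect_equal(tlc_fractions(c(PE = 30, PC = 50, PI = 20)),
               c(PE = 0.30, PC = 0.50, PI = 0.20))
  expect_equal(tlc_fractions(c(PC = 7)), c(PC = 1))
  set.seed(1)
  q <- runif(8)
  expect_equal(sum(tlc_fractions(q)), 1, tolerance = 1e-12)
  expect_error(tlc_fractions(c(0, 0)), "all-zero")
  expect_error(tlc_fractions(c(1, -2)), "negative")
})

test_that("saturation-pair classification implements the carbon/double-bond rule", {
  expect_equal(classify_saturation_pair(34, 2), "more_unsaturated")
  expect_equal(classify_saturation_pair(28, 0), "less_unsaturated")
  expect_equal(classify_saturation_pair(34, 3), "outside_pair")
  expect_equal(classify_saturation_pair(30, 1), "more_unsaturated")
  expect_equal(classify_saturation_pair(32, 1), "less_unsaturated")
  expect_equal(classify_saturation_pair(31, 1), "outside_pair")
  expect_equal(classify_saturation_pair(28, 2), "outside_pair")
  # each (carbons, db) maps to exactly one category: vectorized partition
  grid <- expand.grid(carbons = 24:38, db = 0:4)
  cls <- classify_saturation_pair(grid$carbons, grid$db)
  expect_true(all(cls %in% c("less_unsaturated", "more_unsaturated",
                             "outside_pair")))
  expect_length(cls, nrow(grid))
})

test_that("pooled saturation fraction matches the hand-computed toy table", {
  res <- saturation_fractions(toy_pair_table())
  # (30 + 20) / (10 + 30 + 20 + 20) = 0.625
  expect_equal(res$fractions$frac_more_unsaturated, 0.625)
  expect_equal(res$fractions$pair_total, 80)
  # per-carbon-group fractions when pooling is off
  res2 <- saturation_fractions(toy_pair_table(), pool_carbons = FALSE)
  fr <- res2$fractions
  expect_equal(fr$frac_more_unsaturated[fr$carbon_range == "le30C"], 0.75)
  expect_equal(fr$frac_more_unsaturated[fr$carbon_range == "ge32C"], 0.5)
  # fractions are invariant to global intensity rescaling
  scaled <- toy_pair_table(); scaled$intensity <- scaled$intensity * 37
  expect_equal(saturation_fractions(scaled)$fractions$frac_more_unsaturated,
               0.625)
})

test_that("group comparisons use replicate fractions and handle null cases", {
  tab <- rbind(toy_pair_table("w1", "WT"), toy_pair_table("w2", "WT"),
               toy_pair_table("m1", "mut"), toy_pair_table("m2", "mut"))
  # identical replicate fractions in both groups: difference 0, p = 1
  res <- saturation_fractions(tab)
  cmp <- res$comparisons
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
  # a single replicate leaves the comparison undefined but fractions present
  tab1 <- rbind(toy_pair_table("w1", "WT"), toy_pair_table("m1", "mut"))
  res1 <- saturation_fractions(tab1)
  expect_true(is.na(res1$comparisons$p_value))
  expect_equal(nrow(res1$fractions), 2L)
})

test_that("species outside both pairs never enter the fraction", {
  tab <- toy_pair_table()
  tab <- rbind(tab, data.frame(class = "PE", carbons = 34L,
                               double_bonds = 3L, label = "unlabeled",
                               sample = "s1", intensity = 1e6))
  expect_equal(saturation_fractions(tab)$fractions$frac_more_unsaturated,
               0.625)
})

test_that("per-class abundance shares sum to one and are scale invariant", {
  tab <- toy_pair_table()
  res <- per_species_abundance_grid(tab)
  expect_equal(sum(res$shares$share), 1)
  tab2 <- tab; tab2$intensity <- tab2$intensity * 2
  expect_equal(per_species_abundance_grid(tab2)$shares$share,
               res$shares$share)
  single <- tab[1, ]
  expect_equal(per_species_abundance_grid(single)$shares$share, 1)
})

test_that("flux ratios divide labeled product by labeled precursor", {
  tab <- data.frame(
    class = rep(c("PS", "PE", "PC"), each = 2),
    carbons = 34L, double_bonds = 2L,
    label = rep(c("15N", "unlabeled"), 3),
    sample = "s",
    timepoint = 1,
    intensity = c(200, 400, 50, 100, 10, 80))
  fx <- suppressMessages(flux_ratios(tab))
  pe <- fx[fx$class == "PE", ]
  expect_equal(pe$ratio_to_precursor, 50 / 200)
  expect_equal(pe$ratio_to_unlabeled, 0.5)
  pc <- fx[fx$class == "PC", ]
  expect_equal(pc$ratio_to_precursor, 10 / 50)
  # PS has no precursor
  expect_true(is.na(fx$ratio_to_precursor[fx$class == "PS"]))
})

test_that("zero label at t = 0 leaves precursor ratios undefined, uptake ratio 0", {
  tab <- simulate_labeling(timepoints = c(0, 1))
  fx <- suppressMessages(flux_ratios(tab))
  t0 <- fx[fx$timepoint == 0, ]
  expect_true(all(is.na(t0$ratio_to_precursor)))
  expect_equal(t0$ratio_to_unlabeled[t0$class == "PS"], 0)
})

test_that("precursor-normalized traces are invariant to absolute label uptake", {
  tps <- c(0.5, 1, 2, 4, 8)
  fx1 <- suppressMessages(flux_ratios(simulate_labeling(tps, uptake = 10)))
  fx2 <- suppressMessages(flux_ratios(simulate_labeling(tps, uptake = 37)))
  expect_equal(fx1$ratio_to_precursor, fx2$ratio_to_precursor,
               tolerance = 1e-10)
  # while label uptake itself differs
  expect_false(isTRUE(all.equal(fx1$ratio_to_unlabeled,
                                fx2$ratio_to_unlabeled)))
})

test_that("the closed-form label chain obeys conservation and the k2 = 0 limit", {
  t <- c(0.3, 1, 2.5, 6)
  tr <- label_chain_trace(t, uptake = 4, k1 = 0.9, k2 = 0.4)
  # total label equals integrated influx: PS + PE + PC = uptake * t
  expect_equal(tr$PS + tr$PE + tr$PC, 4 * t, tolerance = 1e-9)
  # equal-rates branch conserves label too
  tr_eq <- label_chain_trace(t, uptake = 4, k1 = 0.7, k2 = 0.7)
  expect_equal(tr_eq$PS + tr_eq$PE + tr_eq$PC, 4 * t, tolerance = 1e-9)
  # no PE -> PC conversion: PC stays zero at all timepoints
  tr0 <- label_chain_trace(t, uptake = 4, k1 = 0.9, k2 = 0)
  expect_equal(tr0$PC, rep(0, length(t)))
  expect_equal(tr0$PS + tr0$PE, 4 * t, tolerance = 1e-9)
})

test_that("species-name parsing extracts class, carbons and double bonds", {
  out <- parse_species_name(c("PE 34:2", "PC 28:0", "PE O-34:2"))
  expect_equal(out$class[1:2], c("PE", "PC"))
  expect_equal(out$carbons[1:2], c(34L, 28L))
  expect_equal(out$double_bonds[1:2], c(2L, 0L))
  expect_true(is.na(out$class[3]))  # ether species fall outside the scheme
})

test_that("lipid table validation flags missing columns and odd chemistry", {
  expect_error(validate_lipid_table(data.frame(class = "PE")),
               "lacks column")
  tab <- toy_pair_table(); tab$carbons[1] <- 17L
  expect_warning(validate_lipid_table(tab), "odd")
  tab2 <- toy_pair_table(); tab2$intensity[1] <- -1
  expect_error(validate_lipid_table(tab2), "negative")
})
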