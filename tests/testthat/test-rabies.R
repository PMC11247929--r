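mk_cells <- function(regions, hemi = "ipsi", layer = "L2/3", gfp = 0,
                     mcherry = 1) {
  data.frame(cell_id = seq_along(regions), region = regions,
             hemisphere = rep_len(hemi, length(regions)),
             layer = rep_len(layer, length(regions)),
             gfp = rep_len(gfp, length(regions)),
             mcherry = rep_len(mcherry, length(regions)),
             stringsAsFactors = FALSE)
}

test_that("input fractions are percentages of input cells only", {
  tab <- mk_cells(c(rep("A", 50), rep("B", 30), rep("C", 20)))
  fr <- input_fractions(tab)
  expect_equal(sum(fr$percent), 100, tolerance = 1e-9)
  expect_equal(fr$percent[match(c("A", "B", "C"), fr$region)], c(50, 30, 20))
  expect_true(all(fr$reported))
  # starters never enter the denominator
  with_starters <- rbind(tab, mk_cells(rep("A", 40), gfp = 1))
  fr2 <- input_fractions(with_starters)
  expect_equal(fr2[order(fr2$region), c("region", "percent")],
               fr[order(fr$region), c("region", "percent")],
               ignore_attr = TRUE)
  expect_error(input_fractions(mk_cells("A", gfp = 1)), "empty tracing")
})

test_that("the reporting filter is strictly greater than 1 percent", {
  tab <- mk_cells(c(rep("big", 99), "edge"))   # edge sits at exactly 1.0%
  fr <- input_fractions(tab)
  expect_equal(fr$percent[fr$region == "edge"], 1)
  expect_false(fr$reported[fr$region == "edge"])
  expect_true(fr$reported[fr$region == "big"])
})

test_that("starter layer distribution normalizes over starters", {
  tab <- rbind(mk_cells(rep("VISp", 2), layer = "L1", gfp = 1),
               mk_cells(rep("VISp", 2), layer = "L5", gfp = 1),
               mk_cells(rep("RSP", 10)))
  d <- starter_layer_distribution(tab)
  expect_equal(sum(d), 1)
  expect_equal(unname(d[c("L1", "L5")]), c(0.5, 0.5))
  only_l1 <- mk_cells(rep("VISp", 3), layer = "L1", gfp = 1)
  expect_equal(unname(starter_layer_distribution(only_l1)), 1)
  expect_error(starter_layer_distribution(mk_cells("A")), "no starter")
})

test_that("local layer fractions use ipsilateral local inputs only", {
  tab <- rbind(mk_cells(rep("VISp", 4), layer = "L5"),
               mk_cells(rep("VISp", 6), layer = "L2/3"),
               mk_cells(rep("VISp", 5), hemi = "contra", layer = "L4"),
               mk_cells(rep("VISp", 3), layer = "L1", gfp = 1),
               mk_cells(rep("LGd", 7), layer = "none"))
  d <- local_layer_fractions(tab)
  expect_equal(sum(d), 1)
  expect_equal(unname(d[c("L2/3", "L5")]), c(0.6, 0.4))
  expect_false("L4" %in% names(d))           # contralateral V1 excluded
  only_l5 <- mk_cells(rep("VISp", 5), layer = "L5")
  expect_equal(unname(local_layer_fractions(only_l5)), 1)
  expect_error(local_layer_fractions(mk_cells("RSP")), "no local input")
})

test_that("generated tables round-trip their layer spec within sampling error", {
  spec <- default_tracing_spec(n_inputs = 5000, n_starters = 50)
  tab <- gen_traced_cells(spec, seed = 9)
  d <- local_layer_fractions(tab)
  truth <- spec$layer_probs$VISp
  expect_lt(max(abs(d[names(truth)] - truth)), 0.03)
  # conservation: input counts sum to the table's input-cell count
  fr <- input_fractions(tab)
  expect_identical(sum(fr$count), sum(tab$mcherry == 1 & tab$gfp == 0))
})
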