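test_that("censored values are imputed at the policy fraction of the limit", {
  pol <- conversion_policy()
  expect_equal(resolve_censored(0, "below_LOQ", 0.90, pol), 0.45)
  expect_equal(resolve_censored(443, "measured", NA, pol), 443)
  expect_error(resolve_censored(0, "below_LOD", 0, pol), "censor_limit")
  expect_error(resolve_censored(0, "below_LOD", NA, pol), "censor_limit")
  # lower/upper bound policies bracket the middle bound
  lo <- resolve_censored(0, "LOQ", 0.9, conversion_policy(censored_fraction = 0))
  hi <- resolve_censored(0, "LOQ", 0.9, conversion_policy(censored_fraction = 1))
  expect_equal(c(lo, hi), c(0, 0.9))
})

test_that("dry-to-wet conversion divides by the factor at full precision", {
  expect_equal(dw_to_ww(40333), 40333 / 4.7)
  # integer reporting uses round-half-away-from-zero
  expect_equal(round_half_up(dw_to_ww(c(40333, 443, 111, 50))),
               c(8581, 94, 24, 11))
  expect_equal(dw_to_ww(0), 0)
  expect_equal(dw_to_ww(47, conversion_policy(dw_to_ww_factor = 10)), 4.7)
})

test_that("normalization leaves no dry-weight value and tags provenance", {
  norm <- normalize_concentrations(seaweed_concentrations())
  expect_false(any(grepl("dry", norm$provenance)))
  sp_tas <- norm[norm$food == "Algae>Seaweed pasta" &
                   norm$substance == "t_arsenic", ]
  expect_equal(sp_tas$value, 40333 / 4.7)
  expect_equal(sp_tas$provenance, "converted_dw")
  # seaweed bacon is eaten dried: value kept as-is
  sb_tas <- norm[norm$food == "Algae>Seaweed bacon" &
                   norm$substance == "t_arsenic", ]
  expect_equal(sb_tas$value, 40333)
  expect_equal(sb_tas$provenance, "measured")
})

test_that("index aggregates internal nodes as means of indexed descendants", {
  norm <- tibble::tibble(
    food = c("Grains>Pasta>Fresh", "Grains>Pasta>Dried"),
    substance = "cadmium", value = c(10, 30), unit = "ug/kg",
    provenance = "measured"
  )
  idx <- build_index(norm)
  hit <- lookup_concentration(idx, "Grains>Pasta", "cadmium")
  expect_equal(hit$value, 20)
  # a single entry propagates unchanged to every ancestor depth
  idx1 <- build_index(norm[1, ])
  for (anc in food_ancestors("Grains>Pasta>Fresh")) {
    expect_equal(lookup_concentration(idx1, anc, "cadmium")$value, 10)
  }
  expect_error(build_index(rbind(norm, norm[1, ])), "duplicate")
})

test_that("internal aggregates equal brute-force means on a random tree", {
  set.seed(7)
  l1 <- paste0("g", 1:4)
  leaves <- tibble::tibble(
    food = replicate(50, paste(c(sample(l1, 1), paste0("m", sample(3, 1)),
                                 paste0("leaf", sample(1e6, 1))),
                               collapse = ">")),
    substance = "lead",
    value = round(runif(50, 1, 100), 3),
    unit = "ug/kg", provenance = "measured"
  )
  leaves <- leaves[!duplicated(leaves$food), ]
  idx <- build_index(leaves)
  internal <- unique(unlist(lapply(leaves$food, function(f) {
    food_ancestors(f, include_self = FALSE)
  })))
  for (node in internal) {
    under <- leaves$value[food_matches_prefix(leaves$food, node)]
    expect_equal(lookup_concentration(idx, node, "lead")$value, mean(under))
  }
})

test_that("lookup falls back to the deepest available ancestor", {
  idx <- tiny_index()
  exact <- lookup_concentration(idx, "Grains>Pasta", "cadmium")
  expect_equal(exact$value, 14)
  expect_equal(exact$provenance, "exact")
  # unknown pasta subtype falls back to the level-2 aggregate
  fb <- lookup_concentration(idx, "Grains>Pasta>Wholegrain", "cadmium")
  expect_equal(fb$value, 14)
  expect_equal(fb$match_depth, 2L)
  expect_match(fb$provenance, "aggregate_depth2")
  expect_warning(
    un <- lookup_concentration(idx, "Drinks>Coffee", "cadmium"),
    "treated as 0"
  )
  expect_equal(un$value, 0)
  expect_equal(un$provenance, "unmatched")
})

test_that("removing a leaf never changes lookups outside its subtree", {
  norm <- tibble::tibble(
    food = c("a>b>x", "a>b>y", "a>c>z"),
    substance = "lead", value = c(5, 15, 40), unit = "ug/kg",
    provenance = "measured"
  )
  full <- build_index(norm)
  pruned <- build_index(norm[-1, ])
  for (q in c("a>c>z", "a>c", "a>c>unseen")) {
    expect_equal(lookup_concentration(pruned, q, "lead")$value,
                 lookup_concentration(full, q, "lead")$value)
  }
})

test_that("censoring treatment bounds order total exposure", {
  s <- tiny_survey()
  # give the records a censored-mercury replacement food
  scn <- scenario("swap", substitution_rule("Grains>Pasta",
                                            "Algae>Seaweed pasta", 0.5))
  s2 <- apply_scenario(s, scn)
  mean_at <- function(frac) {
    idx <- build_index(normalize_concentrations(
      seaweed_concentrations(), conversion_policy(censored_fraction = frac)))
    d <- compute_daily_intakes(s2, idx, "mercury", warn_unmatched = FALSE)
    mean(d$value)
  }
  m <- vapply(c(0, 0.5, 1), mean_at, numeric(1))
  expect_true(m[1] < m[2] && m[2] < m[3])
})
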