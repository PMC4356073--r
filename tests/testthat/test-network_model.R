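test_that("population counts at full scale match the reference area sizes", {
  net <- build_network(tiny_config(), scale = 1.0, seed = 1, wire = FALSE)
  p <- net$pops
  for (d in 0:3) {
    expect_equal(p[paste0("L3e", d), "count"], 2585)
    expect_equal(p[paste0("L3i", d), "count"], 729)
    expect_equal(p[paste0("L5e", d), "count"], 606)
    expect_equal(p[paste0("L5i", d), "count"], 133)
  }
  expect_equal(p["MDSC", "count"], 1000)
  expect_equal(p["VTA", "count"], 1000)
  expect_equal(p["BGrelay", "count"] + p["BGtonic", "count"], 1000)
  for (d in 0:3) {
    expect_equal(p[paste0("PC", d), "count"], 1000)
    expect_equal(p[paste0("MOT", d), "count"], 1000)
  }
})

test_that("scaled counts are rounded and unbuildable scales are refused", {
  net <- build_network(tiny_config(), scale = 0.1, seed = 1, wire = FALSE)
  expect_equal(net$pops["L3e0", "count"], round(0.1 * 2585))
  expect_equal(net$pops["L5i0", "count"], round(0.1 * 133))
  expect_error(build_network(tiny_config(), scale = 0.01, seed = 1,
                             wire = FALSE), "fewer than 10")
})

test_that("wiring is reproducible under a fixed seed", {
  a <- build_network(tiny_config(), scale = 0.1, seed = 42)
  b <- build_network(tiny_config(), scale = 0.1, seed = 42)
  expect_identical(a$syn, b$syn)
  c <- build_network(tiny_config(), scale = 0.1, seed = 43)
  expect_false(identical(a$syn, c$syn))
})

test_that("forbidden within-column L3-L5 pathways have zero synapses", {
  net <- build_network(tiny_config(), scale = 0.1, seed = 1)
  proj <- net$projections
  for (d in 0:3) {
    l3 <- paste0(c("L3e", "L3i"), d); l5 <- paste0(c("L5e", "L5i"), d)
    hits <- proj[(proj$src %in% l3 & proj$dst %in% l5) |
                   (proj$src %in% l5 & proj$dst %in% l3), ]
    expect_equal(nrow(hits), 0L)
  }
})

test_that("realized in-degree matches binomial expectation", {
  net <- build_network(tiny_config(), scale = 0.1, seed = 8)
  pops <- net$pops
  blk <- match("PC0->L3e0", net$projections$name)
  sel <- net$syn$block == blk
  indeg <- tabulate(net$syn$post[sel] - pops["L3e0", "start"] + 1L,
                    pops["L3e0", "count"])
  m <- pops["PC0", "count"]; p <- net$projections$p[blk]
  # 99% binomial bounds on the mean in-degree over the target group
  se <- sqrt(m * p * (1 - p) / pops["L3e0", "count"])
  expect_lt(abs(mean(indeg) - m * p), 2.58 * se * 1.5)
})

test_that("expected synapse count scales with the square of network scale", {
  n1 <- build_network(tiny_config(), scale = 0.1, seed = 2)
  n2 <- build_network(tiny_config(), scale = 0.2, seed = 2)
  r <- length(n2$syn$pre) / length(n1$syn$pre)
  expect_gt(r, 4 * 0.85)
  expect_lt(r, 4 * 1.15)
})

test_that("there are no self-synapses", {
  net <- build_network(tiny_config(), scale = 0.1, seed = 5)
  expect_false(any(net$syn$pre == net$syn$post))
})

test_that("architecture validation passes the default build and flags tampering", {
  net <- build_network(tiny_config(), scale = 0.1, seed = 1)
  rep0 <- validate_architecture(net)
  expect_true(all(rep0$pass))

  cfg_bad <- tiny_config()
  cfg_bad$extra_projections <- list(list(src = "L3e0", dst = "L5e0",
                                         p = 0.1, wname = "l3_ee"))
  bad <- validate_architecture(build_network(cfg_bad, scale = 0.1, seed = 1))
  expect_false(bad$pass[bad$rule == "no within-column L3<->L5 pathway"])

  cfg_missing <- tiny_config()
  cfg_missing$drop_projections <- paste0("MDSC->L5e", 0:3)
  mis <- validate_architecture(build_network(cfg_missing, scale = 0.1, seed = 1))
  expect_false(all(mis$pass[grepl("MDSC->L5e", mis$rule)]))
})

test_that("unknown projection endpoints are a configuration error", {
  cfg <- tiny_config()
  cfg$extra_projections <- list(list(src = "NOPE", dst = "L3e0",
                                     p = 0.1, wname = "l3_ee"))
  expect_error(build_network(cfg, scale = 0.1, seed = 1), "unknown population")
})

test_that("the configuration hash tracks configuration content", {
  cfg <- tiny_config()
  h1 <- config_hash(cfg)
  expect_identical(h1, config_hash(cfg))
  cfg$weights$l3_ee <- cfg$weights$l3_ee * 1.000001
  expect_false(identical(h1, config_hash(cfg)))
})
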