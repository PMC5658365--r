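# build a minimal linear "vector" carrying annotated arms around an insert
stub_vector <- function(up, insert, down, pad = 60) {
  set.seed(nchar(insert) + nchar(up))
  left <- rand_bases(pad); right <- rand_bases(pad)
  v <- ds_seq(paste0(left, up, insert, down, right), "linear", id = "vec")
  v <- add_feature(v, "up", pad, pad + nchar(up))
  add_feature(v, "down", pad + nchar(up) + nchar(insert),
              pad + nchar(up) + nchar(insert) + nchar(down))
}

test_that("adjacent arms (deletion 0) insert without deleting", {
  set.seed(70)
  g <- rand_bases(4000)
  up <- substr(g, 1001, 1100); down <- substr(g, 1101, 1200)
  ins <- rand_bases(250)
  v <- stub_vector(up, ins, down)
  res <- double_crossover(ds_seq(g), v)
  expect_equal(res$deleted_length, 0L)
  expect_equal(ds_length(res$genome), 4000 + 250)
  expect_identical(res$genome$bases, oracle_surgery(g, up, down, ins))
})

test_that("double crossover equals string surgery on random seeded cases", {
  set.seed(71)
  for (case in 1:40) {
    n <- sample(3000:8000, 1)
    g <- rand_bases(n)
    alen <- sample(80:150, 1)
    us <- sample(200:(n %/% 2), 1)
    del <- sample(0:1500, 1)
    ds_pos <- us + alen + del
    if (ds_pos + alen + 100 > n) next
    up <- substr(g, us + 1, us + alen)
    down <- substr(g, ds_pos + 1, ds_pos + alen)
    if (length(gregexpr(up, g, fixed = TRUE)[[1]]) != 1) next
    if (length(gregexpr(down, g, fixed = TRUE)[[1]]) != 1) next
    ins <- rand_bases(sample(50:400, 1))
    v <- stub_vector(up, ins, down)
    res <- double_crossover(ds_seq(g), v)
    expect_equal(res$deleted_length, del)
    expect_identical(res$genome$bases, oracle_surgery(g, up, down, ins))
    expect_equal(ds_length(res$genome), n - del + nchar(ins))
  }
})

test_that("length bookkeeping holds on circular genomes too", {
  set.seed(72)
  cfg <- fixture_config(seed = 72, genome_length = 12000,
                        loci = data.frame(name = "prophage", del_len = 3000),
                        arm_length = 120)
  g <- suppressWarnings(make_toy_genome(cfg))
  arms <- suppressWarnings(extract_arms(g, feature = "prophage",
                                        arm_length = 120))
  ins <- rand_bases(300)
  v <- stub_vector(arms$up$bases, ins, arms$down$bases)
  res <- double_crossover(g, v)
  expect_equal(res$deleted_length, 3000L)
  expect_equal(ds_length(res$genome), 12000 - 3000 + 300)
})

test_that("a prophage-scale 130 kb interval is deleted in one step", {
  cfg <- fixture_config(seed = 73, genome_length = 280000,
                        loci = data.frame(name = "SPbeta", del_len = 130000))
  g <- make_toy_genome(cfg)
  arms <- extract_arms(g, feature = "SPbeta")
  ins <- scrub_all(rand_bases(2000))
  v <- stub_vector(arms$up$bases, ins, arms$down$bases)
  res <- double_crossover(g, v)
  expect_equal(res$deleted_length, 130000L)
  expect_equal(ds_length(res$genome), 280000 - 130000 + 2000)
  # junction check: arms flank the insert exactly once
  b <- res$genome$bases
  expect_equal(length(gregexpr(arms$up$bases, paste0(b, b), fixed = TRUE)[[1]]), 2L)
})

test_that("re-running the same integration is rejected as already integrated", {
  set.seed(74)
  g <- rand_bases(5000)
  up <- substr(g, 2001, 2100); down <- substr(g, 2301, 2400)
  v <- stub_vector(up, rand_bases(200), down)
  res <- double_crossover(ds_seq(g), v)
  expect_error(double_crossover(res$genome, v), "arm context altered")
})

test_that("integration into the reverse-complemented genome mirrors the edit", {
  set.seed(75)
  g <- rand_bases(6000)
  up <- substr(g, 2501, 2600); down <- substr(g, 3001, 3100)
  v <- stub_vector(up, rand_bases(150), down)
  a <- double_crossover(ds_seq(g), v)
  b <- double_crossover(ds_seq(dna_revcomp(g)), v)
  expect_identical(b$strand, "-")
  expect_identical(b$genome$bases, dna_revcomp(a$genome$bases))
  expect_equal(b$deleted_length, a$deleted_length)
})

test_that("arm pathologies are rejected with specific errors", {
  set.seed(76)
  g <- rand_bases(5000)
  up <- substr(g, 1001, 1100); down <- substr(g, 1501, 1600)
  v <- stub_vector(up, rand_bases(100), down)
  expect_error(double_crossover(ds_seq(rand_bases(3000)), v), "up arm not found")
  gdup <- paste0(g, substr(g, 1001, 1100))
  expect_error(double_crossover(ds_seq(gdup), v), "matches 2 genome locations")
  g2 <- sub(down, rand_bases(100), g, fixed = TRUE)
  gopp <- paste0(substr(g2, 1, 3000), dna_revcomp(down), substr(g2, 3001, 5000))
  expect_error(double_crossover(ds_seq(gopp), v), "opposite genome strands")
  swapped <- stub_vector(down, rand_bases(100), up)
  expect_error(double_crossover(ds_seq(g), swapped), "wrong order|overlap")
  circ <- ds_seq(paste0(up, rand_bases(100), down), "circular")
  expect_error(double_crossover(ds_seq(g), circ), "linearized")
})

test_that("linearization demands a unique replication-part cut", {
  cfg <- fixture_config(seed = 77)
  parts <- make_entry_set(cfg)
  fv <- golden_gate(parts, "BsaI")[[1]]$sequence
  lin <- linearize(fv)
  expect_identical(lin$topology, "linear")
  expect_identical(lin$left_end$polarity, "three_prime")
  expect_identical(lin$left_end$overhang, dna_revcomp("GGCC"))
  # vector without any ApaI site: suggest alternatives
  noapa <- fv
  h <- find_sites(fv, "ApaI")
  substr(noapa$bases, h$rec_start + 1L, h$rec_start + 6L) <- "GTGCAC"
  expect_error(linearize(noapa), "no ApaI site")
  # second site -> not unique
  two <- fv
  at <- fv$features$start[fv$features$label == "bla"][1] + 5L
  substr(two$bases, at + 1L, at + 6L) <- "GGGCCC"
  expect_error(linearize(two), "linearization needs a unique site")
  # site inside the integration part -> rejected
  inside <- fv
  cat_at <- fv$features$start[fv$features$label == "cargo"][1] + 20L
  substr(inside$bases, h$rec_start + 1L, h$rec_start + 6L) <- "GTGCAC"
  substr(inside$bases, cat_at + 1L, cat_at + 6L) <- "GGGCCC"
  expect_error(linearize(inside), "cut within integration part")
})

test_that("full pipeline: design, PCR, assembly, linearization, integration round trip", {
  for (seed in c(101, 102)) {
    cfg <- fixture_config(seed = seed, genome_length = 20000,
                          loci = data.frame(name = "target", del_len = 2500))
    g <- make_toy_genome(cfg)
    arms <- extract_arms(g, feature = "target")
    enz <- select_enzyme(list(arms$up, arms$down))
    up_pp <- design_primers(arms$up, "up", enz)
    dn_pp <- design_primers(arms$down, "down", enz)
    up_part <- amplify_arm(arms$up, up_pp)
    dn_part <- amplify_arm(arms$down, dn_pp)
    entry <- make_entry_set(cfg, self_check = FALSE)
    parts <- list(up = up_part, down = dn_part,
                  cargo_resistance = entry$cargo_resistance,
                  destination = entry$destination)
    fv <- golden_gate(parts, enz)[[1]]
    expect_identical(fv$classification, "final_vector")
    lin <- linearize(fv$sequence)
    res <- double_crossover(g, lin)
    expect_equal(res$deleted_length, 2500L)
    # the edit equals independent string surgery with the vector's payload
    f <- g$features
    s <- f$start[f$label == "target"]; e <- f$end[f$label == "target"]
    vf <- lin$features
    ins <- substr(lin$bases, vf$end[vf$label == "up"] + 1L,
                  vf$start[vf$label == "down"])
    want <- paste0(substr(g$bases, 1, s), ins,
                   substr(g$bases, e + 1, ds_length(g)))
    expect_identical(ds_canonical(res$genome), ds_canonical(want))
  }
})
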