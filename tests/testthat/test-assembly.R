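# random fragment with given end overhangs (5' sticky or blunt)
stub_frag <- function(l, r, len = 40, id = NULL) {
  body <- rand_bases(len)
  bases <- paste0(l, body, dna_revcomp(r))
  ds_seq(bases, "linear",
         left_end = if (nzchar(l)) end_spec("five_prime", l) else end_spec("blunt"),
         right_end = if (nzchar(r)) end_spec("five_prime", r) else end_spec("blunt"),
         id = id)
}

# convert to the oracle's fragment description
as_oracle_frag <- function(f) list(bases = f$bases,
                                   l = f$left_end$overhang,
                                   r = f$right_end$overhang)

test_that("a single self-compatible fragment circularizes to one product", {
  set.seed(30)
  body <- rand_bases(50)
  f <- ds_seq(paste0("GCGA", body, "GCGA"), "linear",
              left_end = end_spec("five_prime", "GCGA"),
              right_end = end_spec("five_prime", "TCGC"))
  prods <- assemble_fragments(list(f))
  expect_length(prods, 1L)
  expect_identical(prods[[1]]$topology, "circular")
  expect_equal(ds_length(prods[[1]]), 50 + 4)
})

test_that("product sets equal exhaustive ordering x orientation enumeration", {
  set.seed(31)
  pool <- c("GCGA", "CCAT", "TGAC", "GTTC", "AACG", "TCGC", "ATGG", "")
  n_cases <- 100
  for (case in seq_len(n_cases)) {
    k <- sample(3:5, 1)
    frags <- lapply(seq_len(k), function(i) {
      stub_frag(sample(pool, 1), sample(pool, 1), sample(20:40, 1),
                id = paste0("f", i))
    })
    got <- assemble_fragments(frags, max_cycle = 5L)
    got_keys <- sort(vapply(got, ds_canonical, character(1)))
    want_keys <- oracle_assemble(lapply(frags, as_oracle_frag), max_cycle = 5L)
    expect_identical(got_keys, want_keys, info = paste("case", case))
  }
})

test_that("four fixture parts assemble to exactly one stable final vector carrying bla", {
  cfg <- fixture_config(seed = 42)
  parts <- make_entry_set(cfg)
  prods <- golden_gate(parts, "BsaI")
  cls <- vapply(prods, `[[`, character(1), "classification")
  expect_equal(sum(cls == "final_vector"), 1L)
  fv <- prods[[which(cls == "final_vector")]]
  expect_true(fv$stable)
  expect_true("bla" %in% fv$sequence$features$label)
  expect_equal(nrow(find_sites(fv$sequence, "BsaI")), 0L)
  expect_true("recircularized_destination" %in% cls)
  # every non-final product is re-cleavable (its junctions restore sites)
  expect_false(any(vapply(prods[cls != "final_vector"], `[[`, logical(1), "stable")))
})

test_that("the final vector's part order and marker orientation match the layout", {
  cfg <- fixture_config(seed = 8)
  parts <- make_entry_set(cfg)
  fv <- golden_gate(parts, "BsaI")[[1]]
  f <- fv$sequence$features
  want <- c("up", "cargo", "bsu_marker", "down", "T0", "bla", "oriT", "ori", "T1")
  got <- f[f$label %in% want, ]
  got <- got$label[order(got$start)]
  # cyclic comparison, either direction
  ok <- FALSE
  for (r in seq_along(got) - 1L) {
    rot <- c(got, got)[seq_along(got) + r]
    if (identical(rot, want) || identical(rev(rot), want)) ok <- TRUE
  }
  expect_true(ok)
  expect_true(f$strand[f$label == "cargo"] != f$strand[f$label == "bsu_marker"])
  expect_true(check_seva_compliance(fv$sequence)$pass)
})

test_that("product sets are invariant under part order and input rotation", {
  cfg <- fixture_config(seed = 9)
  parts <- make_entry_set(cfg)
  keys <- function(prods) sort(vapply(prods, function(p)
    ds_canonical(p$sequence), character(1)))
  base_keys <- keys(golden_gate(parts, "BsaI"))
  shuffled <- parts[c(3, 1, 4, 2)]
  expect_identical(keys(golden_gate(shuffled, "BsaI")), base_keys)
  rotated <- parts
  rotated$destination <- ds_rotate(parts$destination, 123)
  rotated$cargo_resistance <- ds_rotate(parts$cargo_resistance, 57)
  expect_identical(keys(golden_gate(rotated, "BsaI")), base_keys)
})

test_that("colony colors follow the reporter features", {
  cfg <- fixture_config(seed = 10)
  parts <- make_entry_set(cfg)
  prods <- golden_gate(parts, "BsaI", xgal = TRUE)
  cls <- vapply(prods, `[[`, character(1), "classification")
  recirc <- prods[[which(cls == "recircularized_destination")]]
  expect_identical(recirc$predicted_color, "red")
  fv <- prods[[which(cls == "final_vector")]]
  expect_identical(fv$predicted_color, "white") # default MCS cargo: no reporter
  # lacZ-alpha cargo turns the final vector blue on X-Gal, white without
  parts_blue <- make_entry_set(fixture_config(seed = 10, cargo_reporter = "lacZalpha"))
  fvb <- golden_gate(parts_blue, "BsaI", xgal = TRUE)[[1]]
  expect_identical(fvb$classification, "final_vector")
  expect_identical(fvb$predicted_color, "blue")
  expect_identical(predict_color(fvb, xgal = FALSE), "white")
  # mkate2 cargo reports light red
  parts_lr <- make_entry_set(fixture_config(seed = 10, cargo_reporter = "mkate2"))
  fvl <- golden_gate(parts_lr, "BsaI")[[1]]
  expect_identical(fvl$predicted_color, "light_red")
})

test_that("an incomplete plan fails with a junction diagnosis", {
  cfg <- fixture_config(seed = 12)
  parts <- make_entry_set(cfg)
  expect_error(golden_gate(parts[c("up", "cargo_resistance", "destination")], "BsaI"),
               "no final vector constructible.*down")
})

test_that("the destination alone recircularizes red without erroring", {
  cfg <- fixture_config(seed = 12)
  parts <- make_entry_set(cfg)
  prods <- golden_gate(list(parts$destination), "BsaI")
  cls <- vapply(prods, `[[`, character(1), "classification")
  expect_true("recircularized_destination" %in% cls)
  i <- which(cls == "recircularized_destination")
  expect_identical(prods[[i]]$predicted_color, "red")
  expect_false(prods[[i]]$stable)
})

test_that("BtgZI is accepted by the engine but draws a warning", {
  cfg <- fixture_config(seed = 13)
  parts <- make_entry_set(cfg)
  expect_warning(prods <- golden_gate(parts, "BtgZI"), "BtgZI")
  cls <- vapply(prods, `[[`, character(1), "classification")
  expect_equal(sum(cls == "final_vector"), 1L)
})
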