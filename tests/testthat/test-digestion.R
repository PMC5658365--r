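make_two_site_plasmid <- function(seed = 1, n1 = 1500, n2 = 1480) {
  set.seed(seed)
  mid1 <- gsub("GGTCTC|GAGACC", "ATATAT", rand_bases(n1))
  mid2 <- gsub("GGTCTC|GAGACC", "ATATAT", rand_bases(n2))
  ds_seq(paste0("GGTCTCTACGT", mid1, "GGTCTCAGGCC", mid2), "circular",
         id = "toy_plasmid")
}

test_that("a circular plasmid with two sites digests into two fragments with conserved length", {
  p <- make_two_site_plasmid()
  fr <- digest(p, "BsaI")
  expect_length(fr, 2L)
  junctions <- 2L
  total <- sum(vapply(fr, ds_length, numeric(1))) - junctions * 4L
  expect_equal(total, ds_length(p))
  # direct coordinate arithmetic: cut windows from find_sites
  h <- find_sites(p, "BsaI")
  expect_equal(nrow(h), 2L)
  w1 <- h$cut_top_pos[1]; w2 <- h$cut_top_pos[2]
  expect_equal(sort(vapply(fr, ds_length, numeric(1))),
               sort(c((w2 - w1) + 4L, (ds_length(p) - (w2 - w1)) + 4L)))
})

test_that("a plasmid with no sites passes through as a single uncut fragment", {
  s <- ds_seq(strrep("ACGT", 200), "circular")
  fr <- digest(s, "BsaI")
  expect_length(fr, 1L)
  expect_true(fr[[1]]$meta$uncut)
  expect_identical(fr[[1]]$topology, "circular")
  expect_identical(fr[[1]]$bases, s$bases)
})

test_that("digesting the C2 polylinker in context yields a 5' GCGA end", {
  m <- mcs_iis_seq("C2")
  ctx <- ds_seq(paste0(strrep("AT", 20), m$bases, strrep("CA", 20)), "linear")
  fr <- digest(ctx, "BsmBI")
  expect_length(fr, 2L)
  expect_identical(fr[[2]]$left_end$polarity, "five_prime")
  expect_identical(fr[[2]]$left_end$overhang, "GCGA")
})

test_that("overlapping cut windows raise an ambiguous-digestion error", {
  # convergent BsaI sites whose 4 nt windows overlap by 2 nt:
  # forward site cuts [7,11), the reverse site at 14 cuts [9,13)
  s <- paste0("GGTCTC", "AAAAAAAA", "GAGACC", strrep("T", 10))
  expect_error(digest(ds_seq(s), "BsaI"), "ambiguous digestion")
})

test_that("overhang compatibility is reverse-complement matching", {
  a <- end_spec("five_prime", "GCGA")
  expect_true(ends_compatible(a, end_spec("five_prime", "TCGC")))
  expect_false(ends_compatible(a, end_spec("five_prime", "GCGA")))
  expect_false(ends_compatible(a, end_spec("three_prime", "TCGC")))
  expect_false(ends_compatible(a, end_spec("five_prime", "TC")))
  expect_true(ends_compatible(end_spec("blunt"), end_spec("blunt")))
})

test_that("re-ligating both junctions of a two-cut plasmid recovers it up to rotation", {
  p <- make_two_site_plasmid(seed = 4)
  fr <- digest(p, "BsaI")
  j <- ligate_fragments(fr[[1]], fr[[2]])
  back <- circularize(j)
  expect_identical(ds_canonical(back), ds_canonical(p))
})

test_that("IIP digestion followed by in-order ligation reconstructs the input exactly", {
  set.seed(21)
  for (i in 1:10) {
    body <- gsub("GGGCCC", "ATATAT", rand_bases(600))
    s <- paste0(substr(body, 1, 200), "GGGCCC", substr(body, 201, 400),
                "GGGCCC", substr(body, 401, 600))
    for (topo in c("linear", "circular")) {
      ds <- ds_seq(s, topo)
      fr <- digest(ds, "ApaI")
      expect_length(fr, if (topo == "linear") 3L else 2L)
      back <- Reduce(ligate_fragments, fr)
      if (topo == "linear") {
        expect_identical(back$bases, ds$bases)
      } else {
        expect_identical(ds_canonical(circularize(back)), ds_canonical(ds))
      }
    }
  }
})

test_that("IIS re-ligation of backbone ends recreates the recognition sites, cross-part junctions do not", {
  cfg <- fixture_config(seed = 3)
  parts <- make_entry_set(cfg)
  # re-ligation: digest the destination and re-join its own two fragments
  fr <- digest(parts$destination, "BsaI")
  relig <- circularize(Reduce(ligate_fragments, fr))
  expect_gt(nrow(find_sites(relig, "BsaI")), 0L)
  # cross-part junctions of the final vector carry no sites
  prods <- golden_gate(parts, "BsaI")
  fv <- prods[[1]]
  expect_identical(fv$classification, "final_vector")
  expect_equal(nrow(find_sites(fv$sequence, "BsaI")), 0L)
  # the junction scars themselves are the fusion windows
  expect_true(all(nchar(fv$junction_scars) == 4L))
})

test_that("blunt and sticky polarity mismatches refuse to ligate", {
  p <- make_two_site_plasmid(seed = 5)
  fr <- digest(p, "BsaI")
  blunt <- ds_seq(rand_bases(50))
  expect_error(ligate_fragments(fr[[1]], blunt), "polarity mismatch")
  expect_error(circularize(blunt_wrong <- ds_seq(rand_bases(30), left_end = end_spec("five_prime", "AAAA"),
                                                 right_end = end_spec("five_prime", "AAAA"))),
               "not mutually compatible")
})
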