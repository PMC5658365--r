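test_that("arm extraction is pure slicing around the interval", {
  set.seed(50)
  g <- ds_seq(rand_bases(5000), "linear", id = "g")
  p <- 2500L
  arms <- extract_arms(g, interval = c(p, p), arm_length = 400)
  expect_identical(arms$up$bases, substr(g$bases, p - 400 + 1, p))
  expect_identical(arms$down$bases, substr(g$bases, p + 1, p + 400))
  # feature-resolved locus on a toy genome with a prophage-like region
  g2 <- ds_seq(rand_bases(6000), "circular")
  g2 <- add_feature(g2, "prophage", 2000L, 4000L)
  a2 <- extract_arms(g2, feature = "prophage", arm_length = 150) |>
    suppressWarnings()
  expect_identical(a2$up$bases, substr(g2$bases, 2000 - 150 + 1, 2000))
  expect_identical(a2$down$bases, substr(g2$bases, 4001, 4150))
})

test_that("asymmetric arm lengths are honored exactly", {
  set.seed(51)
  g <- ds_seq(rand_bases(8000), "linear")
  arms <- extract_arms(g, interval = c(3000, 3100), arm_length = c(550, 580))
  expect_equal(ds_length(arms$up), 550)
  expect_equal(ds_length(arms$down), 580)
})

test_that("arm-length policy: hard floor 70, warning below 400", {
  set.seed(52)
  g <- ds_seq(rand_bases(3000), "linear")
  expect_error(extract_arms(g, interval = c(1500, 1500), arm_length = 60),
               "hard floor")
  expect_warning(extract_arms(g, interval = c(1500, 1500), arm_length = 100),
                 "not recommended")
  expect_error(extract_arms(g, interval = c(10, 20), arm_length = 400),
               "beyond the linear genome")
})

test_that("enzyme selection prefers BsaI and skips blocked enzymes", {
  set.seed(53)
  clean <- ds_seq(scrub_all(rand_bases(500)))
  expect_identical(select_enzyme(list(clean))$name, "BsaI")
  blocked <- ds_seq(paste0(substr(clean$bases, 1, 200), "GGTCTC",
                           substr(clean$bases, 201, 480)))
  e <- select_enzyme(list(blocked))
  expect_identical(e$name, "BbsI")
  rep_ <- attr(e, "report")
  expect_equal(rep_$sites[rep_$enzyme == "BsaI"], 1L)
  # all four blocked -> error advising the storage route
  allsites <- ds_seq(paste0("GGTCTCA", "GAAGACAA", "CGTCTCA", "CACCTGCAAAA",
                            strrep("AT", 30)))
  expect_error(select_enzyme(list(allsites)), "storage-vector route")
})

test_that("designed primers survive the PCR + digestion round trip", {
  set.seed(54)
  for (i in 1:20) {
    arm <- ds_seq(scrub_all(rand_bases(sample(150:400, 1))))
    side <- sample(c("up", "down"), 1)
    enz <- sample(c("BsaI", "BbsI", "BsmBI", "AarI"), 1)
    pp <- design_primers(arm, side, enz)
    prod <- simulate_pcr(arm, pp$fwd, pp$rev, pp$anneal_fwd, pp$anneal_rev)
    frs <- digest(prod, enz)
    expect_length(frs, 3L)
    oh <- if (side == "up") c(junction_overhang("B"), junction_overhang("C"))
          else c(junction_overhang("E"), junction_overhang("F"))
    expect_identical(frs[[2]]$left_end$overhang, oh[1])
    expect_identical(frs[[2]]$right_end$overhang, dna_revcomp(oh[2]))
    expect_identical(frs[[2]]$bases, paste0(oh[1], arm$bases, oh[2]))
  }
})

test_that("annealing regions are exact arm prefixes/suffix complements with Tm >= 60 or 30 nt", {
  set.seed(55)
  arm <- ds_seq(scrub_all(rand_bases(300)))
  pp <- design_primers(arm, "up", "BsaI")
  fa <- substr(pp$fwd, nchar(pp$fwd) - pp$anneal_fwd + 1, nchar(pp$fwd))
  expect_identical(fa, substr(arm$bases, 1, pp$anneal_fwd))
  ra <- substr(pp$rev, nchar(pp$rev) - pp$anneal_rev + 1, nchar(pp$rev))
  expect_identical(ra, substr(dna_revcomp(arm$bases), 1, pp$anneal_rev))
  expect_true(pp$tm_fwd >= 60 || pp$anneal_fwd == 30L)
  expect_true(pp$tm_rev >= 60 || pp$anneal_rev == 30L)
  expect_gte(pp$anneal_fwd, 18L)
})

test_that("AarI tails are longer than BsaI tails by recognition and offset geometry", {
  set.seed(56)
  arm <- ds_seq(scrub_all(rand_bases(300)))
  pa <- design_primers(arm, "up", "AarI")
  pb <- design_primers(arm, "up", "BsaI")
  tail_len <- function(pp) nchar(pp$fwd) - pp$anneal_fwd
  # 7 vs 6 bp recognition plus 4 vs 1 nt cut offset
  expect_equal(tail_len(pa) - tail_len(pb), (7 - 6) + (4 - 1))
})

test_that("storage-route primers are tail-less and name the storage vector", {
  set.seed(57)
  arm <- ds_seq(scrub_all(rand_bases(200)))
  pp <- design_primers(arm, "down", "BsaI", storage_route = TRUE)
  expect_identical(pp$fwd, substr(arm$bases, 1, pp$anneal_fwd))
  expect_identical(pp$storage_vector, "pSEVA243Y")
})

test_that("synthesized polylinkers satisfy their own digestion contract", {
  combos <- list(assembly_enzymes(), c("BsaI"), c("BsaI", "BbsI"),
                 c("BsmBI", "AarI", "BtgZI"))
  for (oh in c("GCGA", "CCAT", "TTAC")) {
    for (enzymes in combos) {
      m <- design_mcs_iis(enzymes, oh)
      for (nm in enzymes) {
        ctx <- ds_seq(paste0(strrep("TA", 15), m$bases, strrep("AT", 15)))
        frs <- digest(ctx, nm)
        expect_length(frs, 2L)
        expect_identical(frs[[2]]$left_end$overhang, oh,
                         info = paste(nm, oh))
      }
      # brute-force verification: only the intended sites exist
      for (nm in enzymes) {
        e <- enzyme(nm)
        want <- oracle_scan(m$bases, e$recognition, e$cut_top, e$cut_bottom)
        expect_equal(nrow(want), 1L, info = paste(nm, oh))
      }
    }
  }
})

test_that("the single-enzyme BsaI polylinker is recognition + 1 nt spacer + overhang", {
  m <- design_mcs_iis("BsaI", "GCGA")
  expect_equal(ds_length(m), 6 + 1 + 4)
  expect_identical(substr(m$bases, 1, 6), "GGTCTC")
  expect_identical(substr(m$bases, 8, 11), "GCGA")
})

test_that("reverse-orientation polylinkers leave the overhang with the upstream part", {
  m <- design_mcs_iis(c("BsaI", "BsmBI"), "GCGA", orientation = "reverse")
  ctx <- ds_seq(paste0(strrep("AT", 15), m$bases, strrep("TA", 15)))
  frs <- digest(ctx, "BsaI")
  expect_length(frs, 2L)
  # the upstream fragment ends with the GCGA window on the forward strand
  up <- frs[[1]]
  expect_identical(substr(up$bases, ds_length(up) - 3L, ds_length(up)), "GCGA")
  expect_identical(up$right_end$overhang, dna_revcomp("GCGA"))
})

test_that("compliance checking flags planted defects and passes the fixture vector", {
  cfg <- fixture_config(seed = 60)
  parts <- make_entry_set(cfg)
  fv <- golden_gate(parts, "BsaI")[[1]]$sequence
  expect_true(check_seva_compliance(fv)$pass)
  # inject an AscI site mid-cargo
  f <- fv$features
  cargo <- f[f$label == "cargo", ][1, ]
  bad <- fv
  at <- cargo$start + 10L
  substr(bad$bases, at + 1L, at + 8L) <- "GGCGCGCC"
  rep_ <- check_seva_compliance(bad)
  expect_false(rep_$pass)
  expect_true(any(rep_$findings$type == "forbidden_site" &
                    rep_$findings$enzyme == "AscI"))
  # but a sanctioned, annotated boundary site passes
  ok <- add_feature(bad, "AscI", at, at + 8L)
  expect_true(check_seva_compliance(ok)$pass)
  # re-orient the marker co-directionally with the cargo
  flip <- fv
  flip$features$strand[flip$features$label == "bsu_marker"] <- "+"
  rep2 <- check_seva_compliance(flip)
  expect_true(any(rep2$findings$type == "marker_orientation"))
  expect_error(check_seva_compliance(ds_seq(rand_bases(100))), "annotations")
})

test_that("nearest-neighbor Tm behaves physically", {
  # higher GC melts higher; longer melts higher; deterministic
  expect_gt(nn_tm("GCGCGCGCGCGCGCGCGC"), nn_tm("ATATATATATATATATAT"))
  expect_gt(nn_tm(strrep("AGTC", 7)), nn_tm(strrep("AGTC", 5)))
  expect_identical(nn_tm("ACGTACGTACGTACGTACGT"), nn_tm("ACGTACGTACGTACGTACGT"))
  # salt and concentration shift Tm in the expected directions
  expect_gt(nn_tm("ACGTACGTACGTACGTACGT", na = 0.2),
            nn_tm("ACGTACGTACGTACGTACGT", na = 0.05))
  expect_gt(nn_tm("ACGTACGTACGTACGTACGT", primer_conc = 5e-6),
            nn_tm("ACGTACGTACGTACGTACGT", primer_conc = 5e-7))
})
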