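test_that("CDK consensus sites are found at 1-based S/T positions", {
  s1 <- scan_cdk_sites(c(p = "AAASPAA"))
  expect_equal(s1$position, 4)
  expect_equal(s1$motif_class, "minimal")

  s2 <- scan_cdk_sites(c(p = "TPAK"))
  expect_equal(s2$position, c(1, 1))
  expect_setequal(s2$motif_class, c("minimal", "full"))

  expect_equal(nrow(scan_cdk_sites(c(p = "AAAA"))), 0)
  expect_error(scan_cdk_sites(c(p = "AC1T")), "non-amino-acid")
})

test_that("overlapping and terminal motifs are all reported", {
  # SPSPxR: sites at 1 and 3; position 3 is also a full site (R at +3)
  s <- scan_cdk_sites(c(p = "SPSPAR"))
  minimal <- s$position[s$motif_class == "minimal"]
  full <- s$position[s$motif_class == "full"]
  expect_equal(minimal, c(1, 3))
  expect_equal(full, 3)
  # [ST]P at the very end: minimal but never full
  tail_site <- scan_cdk_sites(c(p = "AASP"))
  expect_equal(tail_site$position, 3)
  expect_equal(tail_site$motif_class, "minimal")
})

test_that("scanning is case-invariant and full sites are a subset of minimal", {
  expect_equal(scan_cdk_sites(c(p = "aaspga"))["position"],
               scan_cdk_sites(c(p = "AASPGA"))["position"])
  withr::with_seed(43L, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in 1:30) {
      s <- paste(sample(aa, 60, replace = TRUE), collapse = "")
      sites <- scan_cdk_sites(setNames(s, "p"))
      expect_true(all(sites$position[sites$motif_class == "full"] %in%
                        sites$position[sites$motif_class == "minimal"]))
      # every reported acceptor is S/T followed by P
      for (pos in unique(sites$position)) {
        expect_true(substr(s, pos, pos) %in% c("S", "T"))
        expect_equal(substr(s, pos + 1, pos + 1), "P")
      }
    }
  })
})

test_that("sites partition into regions and inter-region bins", {
  ann <- region_annotation("rb1", data.frame(
    region = c("N", "RB-A", "L1", "RB-B", "C"),
    start = c(1, 101, 201, 261, 401),
    end = c(100, 200, 260, 400, 500)))
  sites <- data.frame(protein_id = "rb1",
                      position = c(50, 230, 240, 410, 350),
                      motif_class = "minimal")
  counts <- sites_by_region(sites, ann)
  expect_equal(unname(counts["N"]), 1L)
  expect_equal(unname(counts["L1"]), 2L)
  expect_equal(unname(counts["RB-B"]), 1L)
  expect_equal(unname(counts["C"]), 1L)
  expect_equal(sum(counts), nrow(sites))

  gap <- region_annotation("rb1", data.frame(
    region = c("RB-B", "C"), start = c(1, 201), end = c(100, 300)))
  between <- data.frame(protein_id = "rb1", position = 150,
                        motif_class = "minimal")
  expect_equal(unname(sites_by_region(between, gap)["RB-B/C"]), 1L)

  expect_error(region_annotation("x", data.frame(
    region = c("a", "b"), start = c(1, 5), end = c(10, 20))), "overlap")
})

test_that("alignment mapping round-trips and classifies conservation", {
  # identical sequences with one SP each: a single conserved column
  aln <- c(sp1 = "AASPA", sp2 = "AASPA", sp3 = "AASPA")
  sites <- lapply(aln, function(s) scan_cdk_sites(setNames(gsub("-", "", s), "p")))
  cons <- compare_conservation(aln, sites)
  expect_equal(cons$status, "conserved")
  expect_equal(cons$column, 3)

  # site in one of three sequences: species-specific
  aln2 <- c(sp1 = "AASPA", sp2 = "AAAAA", sp3 = "AAAAA")
  sites2 <- lapply(aln2, function(s) scan_cdk_sites(setNames(s, "p")))
  cons2 <- compare_conservation(aln2, sites2)
  expect_equal(cons2$status, "species-specific")

  # gap-shifted positions map through the alignment: ungapped site 3 of sp1
  # and ungapped site 1 of sp2 share alignment column 3
  aln3 <- c(sp1 = "AASP-", sp2 = "--SPA", sp3 = "AASPA")
  ungapped <- lapply(aln3, function(s) gsub("-", "", s))
  sites3 <- lapply(ungapped, function(s) scan_cdk_sites(setNames(s, "p")))
  expect_equal(sites3$sp1$position, 3)
  expect_equal(sites3$sp2$position, 1)
  cons3 <- compare_conservation(aln3, sites3)
  expect_equal(cons3$column, 3)
  expect_equal(cons3$status, "conserved")
})

test_that("ungapped-to-column mapping is a positional identity", {
  withr::with_seed(47L, {
    for (i in 1:20) {
      res <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 30,
                    replace = TRUE)
      gaps <- sort(sample(1:40, 10))
      gapped <- character(0)
      j <- 1
      for (col in 1:40) {
        if (col %in% gaps) gapped <- c(gapped, "-") else {
          gapped <- c(gapped, res[j]); j <- j + 1
        }
      }
      gapped <- paste(gapped, collapse = "")
      map <- volvocomp:::ungapped_to_column(gapped)
      ungapped <- gsub("-", "", gapped)
      for (pos in sample(nchar(ungapped), 5)) {
        expect_equal(substr(gapped, map[pos], map[pos]),
                     substr(ungapped, pos, pos))
      }
    }
  })
})

test_that("linker lengths and their comparison come from the L1 span", {
  ann <- region_annotation("rb1", data.frame(
    region = c("RB-A", "L1", "RB-B"),
    start = c(1, 100, 160), end = c(99, 150, 300)))
  expect_equal(linker_length(ann), 51)
  point <- region_annotation("rb2", data.frame(
    region = "L1", start = 100, end = 100))
  expect_equal(linker_length(point), 1)
  short <- region_annotation("rb3", data.frame(
    region = c("L1"), start = 100, end = 129))
  expect_equal(linker_length(ann) - linker_length(short), 21)  # shorter by 21
  expect_error(linker_length(region_annotation("x", data.frame(
    region = "RB-A", start = 1, end = 10))), "L1")
})

test_that("region annotations read from TSV", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tregion\tstart\tend",
               "rb1\tRB-A\t1\t99", "rb1\tL1\t100\t150",
               "rb2\tL1\t100\t120"), tf)
  anns <- read_region_annotations(tf)
  expect_setequal(names(anns), c("rb1", "rb2"))
  expect_equal(linker_length(anns$rb1), 51)
  expect_equal(linker_length(anns$rb2), 21)
})
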