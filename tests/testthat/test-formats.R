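test_that("FASTA reading handles wrapping, order, and bad input", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a desc", "AC", "GT", ">b", "GG"), tf)
  seqs <- read_fasta(tf)
  expect_identical(seqs, c(a = "ACGT", b = "GG"))

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", ">a", "GT"), dup)
  expect_error(read_fasta(dup), "duplicate.*a")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("FASTA round-trips and maps U to T only when asked", {
  tf <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(x = "ACGUACGU", y = paste(rep("ACGT", 40), collapse = ""))
  write_fasta(seqs, tf)
  expect_identical(read_fasta(tf), seqs)
  expect_identical(unname(read_fasta(tf, rna_to_dna = TRUE)["x"]), "ACGTACGT")
})

test_that("GFF3 gene models link exons through Parent and sort them", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tID=e2;Parent=m1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\tsrc\tfoo_feature\t5\t6\t.\t+\t.\tID=junk"
  ), tf)
  models <- read_gff3_genes(tf)
  expect_equal(models$gene_id, c("g1", "g1"))
  expect_equal(models$transcript_id, c("m1", "m1"))
  expect_equal(models$start, c(1, 201))   # out-of-order exons sorted
  expect_equal(models$end, c(100, 300))

  orphan <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=m1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=e1;Parent=nosuch"
  ), orphan)
  expect_error(read_gff3_genes(orphan), "nosuch")
})

test_that("GFF3 writer round-trips gene models", {
  toy <- simulate_toy_genome(5, seed = 11)
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(toy$models, tf)
  back <- read_gff3_genes(tf)
  expect_equal(back$gene_id, toy$models$gene_id)
  expect_equal(back$start, toy$models$start)
  expect_equal(back$end, toy$models$end)
})

test_that("Newick reading labels internal nodes deterministically", {
  tr <- read_newick(text = "((A,B),C);")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(tr$Nnode, 2)
  expect_equal(tr$node.label, c("N1", "N2"))  # preorder: root first

  tr2 <- read_newick(text = "((A:1,B:2)X:0.5,C:3)R;")
  expect_equal(sort(tr2$node.label), c("R", "X"))
  expect_equal(sort(tr2$edge.length), c(0.5, 1, 2, 3))

  tr3 <- read_newick(text = "((A,B,C),(D,E));")
  kids <- tabulate(tr3$edge[, 1])
  expect_true(3 %in% kids)  # multifurcation preserved
})

test_that("Newick parse errors carry a character offset", {
  expect_error(read_newick(text = "((A,B),C));"), "character 10")
  expect_error(read_newick(text = "((A,B,C;"), "unclosed")
})

test_that("Newick round-trip preserves topology, labels and lengths", {
  withr::with_seed(5L, {
    for (i in 1:20) {
      tr <- label_internal_nodes(random_tree(sample(3:10, 1)))
      back <- read_newick(text = write_newick(tr))
      expect_equal(back$tip.label, tr$tip.label)
      expect_equal(back$node.label, tr$node.label)
      expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-8)
      expect_true(ape::all.equal.phylo(back, tr, use.edge.length = FALSE))
    }
  })
})

test_that("hit tables parse both kinds, skip comments, report bad lines", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "q1\ts1\t1e-50\t200\tcellular organisms; Eukaryota ;Metazoa"),
             tf)
  h <- read_hit_table(tf, "homology")
  expect_equal(nrow(h), 1)
  expect_equal(h$lineage, "cellular organisms;Eukaryota;Metazoa")
  expect_equal(h$evalue, 1e-50)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1", bad)
  expect_error(read_hit_table(bad, "homology"), "line 1")

  badev <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\tPF1\tabc\t1e-5", badev)
  expect_error(read_hit_table(badev, "domain"), "line 1")

  dom <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\tPF00170\t55.5\t1e-20"), dom)
  d <- read_hit_table(dom, "domain")
  expect_equal(d$domain_id, "PF00170")
  expect_equal(d$bitscore, 55.5)
})

test_that("hit tables and family matrices round-trip", {
  hh <- homology_row(c("q1", "q2"), c("s1", "s2"), c(1e-10, 2e-4),
                     c("a;b;c", "a;b"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hh, tf, "homology")
  expect_equal(read_hit_table(tf, "homology"), hh)

  mat <- matrix(0:5, nrow = 3, dimnames = list(paste0("f", 1:3), c("A", "B")))
  storage.mode(mat) <- "integer"
  mf <- withr::local_tempfile(fileext = ".tsv")
  write_family_matrix(mat, mf)
  expect_identical(read_family_matrix(mf), mat)

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family\tA", "f1\t-1"), neg)
  expect_error(read_family_matrix(neg), "non-negative")
})
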