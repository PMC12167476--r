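test_that("default library reproduces the requested composition exactly", {
  lib <- build_default_library(n_lnc_genes = 12, guides_per_gene = 10,
                               n_ntc = 7, n_positive_genes = 2, seed = 1)
  tab <- table(lib$guide_class)
  expect_equal(unname(tab[["tss_targeting"]]), 120)
  expect_equal(unname(tab[["non_targeting"]]), 7)
  expect_equal(unname(tab[["positive_control"]]), 20)
  expect_equal(nrow(lib), 147)
  expect_false(anyDuplicated(lib$spacer) > 0)
  expect_true(all(grepl("^[ACGT]{20}$", lib$spacer)))
  # zero case
  expect_equal(nrow(build_default_library(0, 10, 0, 0, seed = 1)), 0)
  # negative counts rejected
  expect_error(build_default_library(-1, 10, 0, 0, seed = 1),
               "non-negative")
})

test_that("library generation is deterministic given the seed", {
  a <- build_default_library(5, 10, 20, 1, seed = 7)
  b <- build_default_library(5, 10, 20, 1, seed = 7)
  expect_identical(a, b)
  c <- build_default_library(5, 10, 20, 1, seed = 8)
  expect_false(identical(a$spacer, c$spacer))
})

test_that("library validation enforces the guide-record invariants", {
  base <- data.frame(guide_id = c("a", "b"),
                     spacer = c("ACGTACGTACGTACGTACGT",
                                "TGCATGCATGCATGCATGCA"),
                     guide_class = c("tss_targeting", "non_targeting"),
                     target_gene_id = c("G1", ""))
  expect_s3_class(guide_library(base), "guide_library")

  dup_id <- base; dup_id$guide_id <- c("a", "a")
  expect_error(guide_library(dup_id), "duplicate guide_id")

  bad_spacer <- base; bad_spacer$spacer[1] <- "acgtACGTACGTACGTACGT"
  expect_error(guide_library(bad_spacer), "invalid spacer")
  short_spacer <- base; short_spacer$spacer[1] <- "ACGTACGTACGTACGTAC"
  expect_error(guide_library(short_spacer), "invalid spacer")

  ntc_target <- base; ntc_target$target_gene_id[2] <- "G9"
  expect_error(guide_library(ntc_target), "empty target_gene_id")
  no_target <- base; no_target$target_gene_id[1] <- ""
  expect_error(guide_library(no_target), "non-empty target_gene_id")

  dup_spacer <- base; dup_spacer$spacer[2] <- dup_spacer$spacer[1]
  expect_error(guide_library(dup_spacer), "duplicated spacer")
  expect_warning(guide_library(dup_spacer, duplicate_spacers = "warn"),
                 "duplicated spacer")
})

test_that("library TSV round trip preserves the design", {
  lib <- build_default_library(3, 4, 5, 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library_tsv(lib, path)
  back <- read_library_tsv(path, guides_per_gene = 4)
  expect_identical(as.data.frame(back), as.data.frame(lib))
})

test_that("classification reproduces the canonical category geometries", {
  # intergenic: own promoter far from every neighbor, no overlap
  lnc <- list(gene_id = "L", chrom = "chr1", start = 50000, end = 51000,
              strand = "+", biotype = "lncRNA", exons = NULL)
  nb <- data.frame(gene_id = "N", chrom = "chr1", start = 55000,
                   end = 57000, strand = "+", biotype = "protein_coding")
  expect_equal(classify_lnc_category(lnc, nb), "intergenic")

  # antisense: opposite-strand overlap with the neighbor's locus
  lnc2 <- list(gene_id = "L2", chrom = "chr1", start = 10000, end = 12000,
               strand = "-", biotype = "lncRNA", exons = NULL)
  nb2 <- data.frame(gene_id = "N2", chrom = "chr1", start = 9000,
                    end = 15000, strand = "+", biotype = "protein_coding")
  expect_equal(classify_lnc_category(lnc2, nb2), "antisense")

  # bidirectional: opposite strand, TSSs within 1 kb, no overlap
  lnc3 <- list(gene_id = "L3", chrom = "chr1", start = 9500, end = 10601,
               strand = "-", biotype = "lncRNA", exons = NULL)
  nb3 <- data.frame(gene_id = "N3", chrom = "chr1", start = 10000 + 700,
                    end = 13000, strand = "+", biotype = "protein_coding")
  expect_equal(classify_lnc_category(lnc3, nb3), "bidirectional")

  # intronic: fully inside one intron of the neighbor
  ann <- gene_annotation(data.frame(
    gene_id = "H", chrom = "chr1", start = 15000, end = 30000,
    strand = "+", biotype = "protein_coding"))
  ann$exons[[1]] <- cbind(c(15000, 25000), c(20000, 30000))
  lnc4 <- list(gene_id = "L4", chrom = "chr1", start = 21000, end = 21800,
               strand = "+", biotype = "lncRNA", exons = NULL)
  expect_equal(classify_lnc_category(lnc4, ann), "intronic")

  # protein-coding biotype wins regardless of geometry
  pc <- list(gene_id = "P", chrom = "chr1", start = 10000, end = 12000,
             strand = "-", biotype = "protein_coding", exons = NULL)
  expect_equal(classify_lnc_category(pc, nb2), "protein_coding")
})

test_that("classification precedence, errors, and partition property hold", {
  # antisense dominates bidirectional: overlapping and TSSs close
  lnc <- list(gene_id = "L", chrom = "chr1", start = 10000, end = 10900,
              strand = "-", biotype = "lncRNA", exons = NULL)
  nb <- data.frame(gene_id = "N", chrom = "chr1", start = 10500,
                   end = 12000, strand = "+", biotype = "protein_coding")
  expect_equal(classify_lnc_category(lnc, nb), "antisense")

  # neighbor on another chromosome is an argument error
  nb_chr2 <- nb; nb_chr2$chrom <- "chr2"
  expect_error(classify_lnc_category(lnc, nb_chr2), "chromosome")

  # same-strand close promoter with no category is a named error
  lnc_none <- list(gene_id = "LX", chrom = "chr1", start = 10000,
                   end = 10400, strand = "+", biotype = "lncRNA",
                   exons = NULL)
  nb_same <- data.frame(gene_id = "N", chrom = "chr1", start = 10500,
                        end = 12000, strand = "+",
                        biotype = "protein_coding")
  expect_error(classify_lnc_category(lnc_none, nb_same), "LX")

  # partition: every fixture gene gets exactly its one expected label
  fix <- make_category_annotation(n_antisense = 3, n_intergenic = 2,
                                  n_protein = 2, n_intronic = 2,
                                  n_bidirectional = 2)
  got <- classify_annotation(fix$annotation, fix$hits)
  expect_equal(got$category, fix$expected)
})

test_that("GTF annotation import maps coordinates, biotypes, and exons", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "G1"; gene_biotype "lncRNA";'
  attr2 <- 'gene_id "G2"; gene_biotype "protein_coding";'
  writeLines(c(
    paste("chr1", "src", "gene", "101", "500", ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "src", "gene", "1001", "4000", ".", "-", ".", attr2,
          sep = "\t"),
    paste("chr1", "src", "exon", "1001", "1500", ".", "-", ".", attr2,
          sep = "\t"),
    paste("chr1", "src", "exon", "3001", "4000", ".", "-", ".", attr2,
          sep = "\t")), gtf)
  ann <- read_annotation_gtf(gtf)
  ann <- ann[order(ann$gene_id), ]
  # 1-based closed GTF -> 0-based half-open
  expect_equal(ann$start, c(100, 1000))
  expect_equal(ann$end, c(500, 4000))
  expect_equal(ann$biotype, c("lncRNA", "protein_coding"))
  expect_equal(ann$tss, c(100, 3999))
  expect_equal(ann$exons[[2]], cbind(c(1000, 3000), c(1500, 4000)))
})

test_that("BED annotation reader maps columns and exons correctly", {
  genes <- withr::local_tempfile(fileext = ".bed")
  exons <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500\tG1\tlncRNA\t+",
               "chr1\t1000\t4000\tG2\tprotein_coding\t-"), genes)
  writeLines(c("chr1\t1000\t1500\tG2", "chr1\t3000\t4000\tG2"), exons)
  ann <- read_annotation_bed(genes, exons)
  expect_equal(ann$gene_id, c("G1", "G2"))
  expect_equal(ann$tss, c(100, 3999))
  expect_equal(ann$exons[[2]], cbind(c(1000, 3000), c(1500, 4000)))
  expect_null(ann$exons[[1]])
})
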