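test_that("abundance tables round-trip through delimited text", {
  v <- matrix(c(0.6, 0.4, 0.3, 0.7, 0.2, 0.8, 0.5, 0.5), nrow = 2,
              dimnames = list(c("fam_A", "fam_B"), paste0("T", 1:4)))
  f <- tempfile(fileext = ".tsv")
  write.table(cbind(taxon = rownames(v), as.data.frame(v)), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  tab <- read_abundance_table(f)
  expect_equal(dim(tab), c(2L, 4L))
  expect_equal(unname(tab$values), unname(v))
  expect_identical(tab$taxa, rownames(v))
  expect_identical(tab$samples, colnames(v))
})

test_that("percent-scale input is rescaled to proportions on request", {
  v <- matrix(c(60, 40, 30, 70), nrow = 2,
              dimnames = list(c("a", "b"), c("T1", "T2")))
  f <- tempfile(fileext = ".csv")
  write.table(cbind(taxon = rownames(v), as.data.frame(v)), f, sep = ",",
              quote = FALSE, row.names = FALSE)
  tab <- read_abundance_table(f, normalize = TRUE)
  expect_equal(unname(colSums(tab$values)), c(1, 1))
  # normalization is idempotent
  tab2 <- abundance_table(tab$values, normalize = TRUE)
  expect_equal(tab2$values, tab$values)
})

test_that("malformed tables are rejected with informative errors", {
  expect_error(abundance_table(matrix(c(1, -0.1), 1, 2)), "negative")
  expect_error(abundance_table(matrix(1, 2, 1, dimnames = list(c("x", "x"),
                                                               "s"))),
               "duplicate taxon")
  expect_error(abundance_table(matrix(c(1, NA), 1, 2)), "missing")
  expect_error(abundance_table(matrix(c(1, 0), 2, 1), normalize = TRUE),
               NA)
  expect_error(abundance_table(matrix(0, 2, 1), normalize = TRUE),
               "empty sample")
  f <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tS1\tS2", "a\t0.5\toops", "b\t0.5\t1"), f)
  expect_error(read_abundance_table(f), "non-numeric cell.*'a'.*S2")
})

test_that("a time header row is recognized", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tT1\tT2\tT3",
               "day\t2\t6\t8",
               "a\t0.5\t0.4\t0.3",
               "b\t0.5\t0.6\t0.7"), f)
  tab <- read_abundance_table(f)
  expect_equal(tab$times, c(2, 6, 8))
  expect_equal(dim(tab), c(2L, 3L))
})

test_that("mothur shared layout is transposed and closed", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("label\tGroup\tnumOtus\totu1\totu2",
               "0.03\tT1\t2\t30\t70",
               "0.03\tT2\t2\t10\t90"), f)
  tab <- read_abundance_table(f, dialect = "shared")
  expect_identical(tab$taxa, c("otu1", "otu2"))
  expect_identical(tab$samples, c("T1", "T2"))
  expect_equal(unname(tab$values[, "T1"]), c(0.3, 0.7))
})

test_that("phase designs parse, validate, and respect temporal order", {
  tab <- abundance_table(random_table(3, 30))
  d <- read_phase_design("before=1..12, during=13..15, after=16..30", tab)
  expect_length(d$before, 12)
  expect_length(d$during, 3)
  expect_length(d$after, 15)
  expect_error(read_phase_design("before=1..12, during=13..15, after=16..29",
                                 tab), "cover")
  expect_error(read_phase_design("before=16..30, during=13..15, after=1..12",
                                 tab), "temporal order")
  expect_error(read_phase_design("before=1..1, during=2..15, after=16..30",
                                 tab), ">= 2")
  expect_error(phase_design(1:12, 12:15, 16:30, 30), "overlap")
})

test_that("phase designs load from a sample-phase file", {
  tab <- abundance_table(random_table(2, 6))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tphase",
               paste(tab$samples, rep(c("before", "during", "after"),
                                      c(2, 2, 2)), sep = "\t")), f)
  d <- read_phase_design(f, tab)
  expect_equal(d$during, 3:4)
})

test_that("edge lists and result bundles round-trip on disk", {
  edges <- data.frame(source = c("a", "b"), target = c("b", "c"),
                      sign = c(1, -1), strength = c(0.5, -1.2),
                      n_pos = c(95, 2), n_neg = c(1, 97),
                      n_present = c(100, 100), stringsAsFactors = FALSE)
  net <- signed_network(edges)
  dir <- tempfile()
  cls <- data.frame(taxon = c("a", "b", "c"), abundance_class = "HA",
                    stringsAsFactors = FALSE)
  files <- write_results(dir, classification = cls,
                         networks = list(before = net),
                         summaries = list(note = data.frame(x = 1)))
  expect_true(all(file.exists(files)))
  back <- read_edge_csv(file.path(dir, "network_before_edges.csv"))
  expect_equal(back$edges[, colnames(edges)], edges)
  cls_back <- read.table(file.path(dir, "classification.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(cls_back), 3)
  g <- igraph::read_graph(file.path(dir, "network_before.graphml"),
                          format = "graphml")
  expect_equal(igraph::ecount(g), 2)
})

test_that("annotation tables validate ranges and parse pathway lists", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tgc_percent\tgenome_size_mb\tdomain\tpathways",
               "a\t55.2\t3.1\tArchaea\tp1;p2",
               "b\tNA\t2.0\tBacteria\tp2"), f)
  ann <- read_annotations(f)
  expect_equal(ann$pathways[[1]], c("p1", "p2"))
  expect_true(is.na(ann$gc_percent[2]))
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tgc_percent", "a\t120"), f2)
  expect_error(read_annotations(f2), "gc_percent")
})
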