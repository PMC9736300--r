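# A tiny deterministic expression fixture: 5 genes, 2 tissues, 2 samples
# per (tissue, sex) cell.
tiny_expression <- function() {
  genes <- paste0("g", 1:5)
  attrs <- data.frame(
    sample_id = c("t1_M_1", "t1_M_2", "t1_F_1", "t1_F_2",
                  "t2_M_1", "t2_M_2", "t2_F_1", "t2_F_2"),
    tissue = rep(c("t1", "t2"), each = 4),
    sex = rep(c("male", "male", "female", "female"), 2),
    stringsAsFactors = FALSE
  )
  set.seed(51)
  tpm <- matrix(rlnorm(5 * 8, 2, 1), 5, 8,
                dimnames = list(genes, attrs$sample_id))
  list(tpm = tpm, attrs = attrs)
}

test_that("mean_expression averages TPM over the (tissue, sex) samples", {
  fx <- tiny_expression()
  ge <- mean_expression(fx$tpm, fx$attrs, "t1", "male")
  # brute-force double loop
  for (g in rownames(fx$tpm))
    expect_equal(ge[[g]], (fx$tpm[g, "t1_M_1"] + fx$tpm[g, "t1_M_2"]) / 2)
  one <- fx$attrs[fx$attrs$sample_id == "t2_F_1", ]
  expect_equal(unname(mean_expression(fx$tpm, one, "t2", "female")),
               unname(fx$tpm[, "t2_F_1"]))
  expect_error(mean_expression(fx$tpm, fx$attrs, "t9", "male"), "t9")
})

test_that("expression_sex_bias is a log2 ratio, undefined at zero", {
  expect_equal(expression_sex_bias(7, 7), 0)
  expect_equal(expression_sex_bias(8, 2), 2)
  expect_true(is.na(expression_sex_bias(8, 0)))
  set.seed(52)
  m <- runif(20, 0.1, 50); f <- runif(20, 0.1, 50)
  expect_equal(expression_sex_bias(m, f), -expression_sex_bias(f, m))
})

test_that("gene_set_activity is the geometric mean of member expression", {
  fx <- tiny_expression()
  fx$tpm[, ] <- 1
  fx$tpm["g1", c("t1_M_1", "t1_M_2")] <- 4
  fx$tpm["g2", c("t1_M_1", "t1_M_2")] <- 9
  expect_equal(gene_set_activity(fx$tpm, fx$attrs, c("g1", "g2"), "t1", "male"), 6)
  expect_equal(gene_set_activity(fx$tpm, fx$attrs, "g1", "t1", "male"), 4)

  # 37-gene lognormal set against the exp(mean(log)) oracle
  set.seed(53)
  genes <- paste0("mt", 1:37)
  big <- matrix(rlnorm(37 * 4, 1, 1.5), 37, 4,
                dimnames = list(genes, paste0("s", 1:4)))
  attrs <- data.frame(sample_id = paste0("s", 1:4), tissue = "t",
                      sex = c("male", "male", "female", "female"))
  ge <- rowMeans(big[, 1:2])
  expect_equal(gene_set_activity(big, attrs, genes, "t", "male"),
               exp(mean(log(ge))))

  expect_error(gene_set_activity(big, attrs, c("mt1", "nope"), "t", "male"),
               "nope")
  big["mt1", 1:2] <- 0
  expect_warning(
    gsa <- gene_set_activity(big, attrs, genes, "t", "male"), "zero mean")
  expect_true(is.na(gsa))
  expect_message(
    floored <- gene_set_activity(big, attrs, genes, "t", "male", eps = 0.01),
    "floor")
  expect_false(is.na(floored))
})

test_that("ASB equals the mean of member ESBs and is scale invariant", {
  fx <- tiny_expression()
  genes <- rownames(fx$tpm)
  asb <- activity_sex_bias(fx$tpm, fx$attrs, genes, "t1")
  esb <- expression_sex_bias(mean_expression(fx$tpm, fx$attrs, "t1", "male"),
                             mean_expression(fx$tpm, fx$attrs, "t1", "female"))
  expect_equal(asb, mean(esb), tolerance = 1e-9)

  # equal male/female expression: zero bias; doubling male expression: +1
  sym <- fx$tpm
  sym[, 5:8] <- sym[, 1:4]
  attrs2 <- fx$attrs
  attrs2$tissue <- "t1"
  attrs2$sex <- rep(c("male", "female"), each = 4)
  sym <- sym[, attrs2$sample_id]
  expect_equal(activity_sex_bias(sym, attrs2, genes, "t1"), 0)
  sym[, attrs2$sex == "male"] <- 2 * sym[, attrs2$sex == "male"]
  expect_equal(activity_sex_bias(sym, attrs2, genes, "t1"), 1)

  # global TPM rescaling changes neither ESB nor ASB
  expect_equal(activity_sex_bias(3.7 * fx$tpm, fx$attrs, genes, "t1"), asb)
  summ <- tissue_expression_summary(fx$tpm, fx$attrs)
  summ_scaled <- tissue_expression_summary(3.7 * fx$tpm, fx$attrs)
  expect_equal(summ_scaled$esb, summ$esb)

  # sample and gene order do not matter
  perm <- fx$tpm[sample(5), sample(8)]
  expect_equal(activity_sex_bias(perm, fx$attrs, genes, "t1"), asb)
})

test_that("expression matrix and sample attribute readers parse GTEx-style layouts", {
  dir <- withr::local_tempdir()
  mat_path <- file.path(dir, "tpm.tsv")
  writeLines(c(
    "gene_id\tgene_symbol\ts1\ts2\ts3\ts4",
    "ENSG1\tMT-CO1\t1.5\t2.5\t3\t4",
    "ENSG2\tACTB\t10\t20\t30\t40"
  ), mat_path)
  tpm <- read_expression_matrix(mat_path)
  expect_equal(dim(tpm), c(2L, 4L))
  expect_equal(tpm["ENSG1", "s2"], 2.5)
  expect_equal(attr(tpm, "symbols")[["ENSG2"]], "ACTB")

  # GCT-style preamble is tolerated
  gct_path <- file.path(dir, "tpm.gct")
  writeLines(c("#1.2", "2\t4",
               readLines(mat_path)), gct_path)
  expect_equal(unname(read_expression_matrix(gct_path)), unname(tpm))

  attr_path <- file.path(dir, "attrs.tsv")
  writeLines(c("sample_id\ttissue\tsex",
               "s1\tbrain_cortex\tMale", "s2\tbrain_cerebellum\tFemale",
               "s3\tliver\tmale", "s4\tliver\tfemale"), attr_path)
  attrs <- read_sample_attributes(attr_path)
  expect_equal(attrs$sex, c("male", "female", "male", "female"))

  # sub-tissue pooling via a tissue map
  ge <- mean_expression(tpm, attrs, "brain",
                        "male", tissue_map = c(brain_cortex = "brain",
                                               brain_cerebellum = "brain"))
  expect_equal(unname(ge), unname(tpm[, "s1"]))

  writeLines(c("gene_id\tgene_symbol\ts1", "ENSG1\tA\t1", "ENSG1\tB\t2"),
             mat_path)
  expect_error(read_expression_matrix(mat_path), "duplicated")
})
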