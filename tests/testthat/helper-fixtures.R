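# in-code fixtures shared across test files

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# 3 genes x 4 samples expression TSV
expr_fixture_lines <- function() c(
  "gene\tS1\tS2\tS3\tS4",
  "GENEA\t1.5\t2.5\t3.5\t4.5",
  "GENEB\t0.1\t0.2\t0.3\t0.4",
  "GENEC\t-1\t0\t1\t2"
)

# same table in GEO series-matrix dress
series_fixture_lines <- function() c(
  "!Series_title\t\"toy\"",
  "!Series_platform_id\t\"GPL0\"",
  "!Sample_characteristics\t\"a\"\t\"b\"\t\"c\"\t\"d\"",
  "!Sample_source\t\"x\"\t\"x\"\t\"x\"\t\"x\"",
  "!series_matrix_table_begin",
  "\"ID_REF\"\t\"S1\"\t\"S2\"\t\"S3\"\t\"S4\"",
  "\"GENEA\"\t1.5\t2.5\t3.5\t4.5",
  "\"GENEB\"\t0.1\t0.2\t0.3\t0.4",
  "\"GENEC\"\t-1\t0\t1\t2",
  "!series_matrix_table_end",
  "!Series_end\t\"1\""
)

meth_fixture_lines <- function() c(
  "probe_id\tS1\tS2\tS3\tS4",
  "cg0000001\t0.1\t0.2\t0.3\t0.4",
  "cg0000002\t0.9\tNA\t0.7\t0.6",
  "cg0000003\t0.5\t0.5\tNA\t0.5"
)

annotation_fixture_lines <- function() c(
  "probe_id\tUCSC_RefGene_Name\tUCSC_RefGene_Group",
  "cg0000001\tGENEA;GENEA\tTSS200;Body",
  "cg0000002\tGENEA;GENEB\tBody;TSS1500",
  "cg0000003\t\t",
  "cg0000004\tGENEB\t3'UTR"
)

# a paired dataset with planted structure, small enough for fast tests
tiny_dataset <- function(n = 60, G = 6, seed = 7, ...) {
  generate_dataset(generator_config(
    n_samples = n, n_genes = G, probes_per_gene = c(3, 6),
    target_r2 = c(0.2, 0.6), n_causal = 2, fraction_s_and_c = 0.2,
    scale = "m", seed = seed, ...))
}

# hand-buildable paired dataset from explicit matrices
paired_from_matrices <- function(expr, meth, scale = "m") {
  expr <- structure(expr, class = c("expr_matrix", class(expr)))
  meth <- structure(meth, scale = scale, class = c("meth_matrix", class(meth)))
  align_samples(expr, meth)
}

# design built straight from X and y, bypassing matrix plumbing
design_from_xy <- function(X, y, gene = "G1") {
  if (is.null(colnames(X))) colnames(X) <- sprintf("cg%07d", seq_len(ncol(X)))
  structure(
    list(gene = gene, X = X, y = y, probe_ids = colnames(X),
         n_complete = nrow(X), p = ncol(X), dropped = character()),
    class = "gene_design")
}
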