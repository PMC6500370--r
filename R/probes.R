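REGION_GROUPS <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
PROMOTER_GROUPS <- c("TSS1500", "TSS200", "5UTR", "1stExon")

# normalize manifest spellings like 5'UTR -> 5UTR
normalize_group <- function(g) {
  g <- gsub("'", "", g, fixed = TRUE)
  bad <- setdiff(unique(g), REGION_GROUPS)
  if (length(bad) > 0)
    stop(sprintf("unknown region group(s): %s", paste(bad, collapse = ", ")))
  g
}

#' Load a 450K-manifest-like probe annotation table
#'
#' Expects a CSV or TSV with columns for the probe id, a semicolon-joined
#' gene list (`UCSC_RefGene_Name`), and a semicolon-joined region-group list
#' (`UCSC_RefGene_Group`), as in the Illumina 450K manifest convention where
#' the two lists are aligned element by element. Per-probe (gene, group)
#' pairs are deduplicated; probes with an empty gene field are retained but
#' map to no gene.
#'
#' @param path path to the annotation file; the delimiter is taken from the
#'   extension (`.csv` vs anything else = tab).
#' @param probe_col,gene_col,group_col column names; defaults follow the
#'   manifest. The first column is used as probe id if `probe_col` is absent.
#' @return A `probe_annotation`: data frame with columns `probe_id`, `gene`,
#'   `group` (one row per retained pair), plus an attribute `probes` listing
#'   every probe seen (including gene-less ones).
#' @export
load_probe_annotation <- function(path,
                                  probe_col = "probe_id",
                                  gene_col = "UCSC_RefGene_Name",
                                  group_col = "UCSC_RefGene_Group") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", comment.char = "#",
                           quote = "\"", check.names = FALSE)
  if (!probe_col %in% names(tab)) probe_col <- names(tab)[1]
  for (cl in c(gene_col, group_col))
    if (!cl %in% names(tab)) stop(sprintf("annotation lacks column '%s'", cl))
  ids <- trimws(tab[[probe_col]])
  genes <- strsplit(trimws(tab[[gene_col]]), ";", fixed = TRUE)
  groups <- strsplit(trimws(tab[[group_col]]), ";", fixed = TRUE)
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    gn <- genes[[i]]; gr <- groups[[i]]
    gn <- gn[nzchar(gn)]; gr <- gr[nzchar(gr)]
    if (length(gn) == 0) next
    if (length(gn) != length(gr))
      stop(sprintf("probe %s: %d genes but %d region groups",
                   ids[i], length(gn), length(gr)))
    pair <- unique(data.frame(probe_id = ids[i], gene = gn,
                              group = normalize_group(gr),
                              stringsAsFactors = FALSE))
    rows[[i]] <- pair
  }
  ann <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(ann))
    ann <- data.frame(probe_id = character(), gene = character(),
                      group = character(), stringsAsFactors = FALSE)
  structure(ann, probes = unique(ids), class = c("probe_annotation", "data.frame"))
}

#' Read a probe exclusion list
#'
#' Plain text, one probe id per line; `#` starts a comment.
#'
#' @param path path to the list.
#' @return Character vector of probe ids.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Classify array probes into methylation vs S&C sets
#'
#' Probes on the exclusion list — those with potential SNP effects or
#' cross-hybridization effects — are classed `s_and_c`; every other probe is
#' a `methylation` probe. The union of the two is the "all probes" set. An
#' empty exclusion list makes every probe a methylation probe.
#'
#' @param probe_ids probes present on the array / in the methylation matrix.
#' @param exclusion_list character vector of excluded probe ids (or a file
#'   path readable by [read_exclusion_list()]).
#' @return A `probe_classification`: data frame with columns `probe_id` and
#'   `class`, one row per input probe, with attribute `provenance`.
#' @export
classify_probes <- function(probe_ids, exclusion_list = character()) {
  provenance <- NA_character_
  if (length(exclusion_list) == 1 && file.exists(exclusion_list)) {
    provenance <- exclusion_list
    exclusion_list <- read_exclusion_list(exclusion_list)
  }
  structure(
    data.frame(probe_id = probe_ids,
               class = ifelse(probe_ids %in% exclusion_list,
                              "s_and_c", "methylation"),
               stringsAsFactors = FALSE),
    provenance = provenance,
    class = c("probe_classification", "data.frame")
  )
}

#' Build the gene-to-probe map
#'
#' Joins the annotation with the probe classification and restricts to
#' probes actually present in the methylation matrix. A probe annotated to
#' several genes contributes to every one of them; within a gene, probes are
#' ordered by ascending probe id for reproducible design matrices.
#'
#' @param annotation a `probe_annotation` (or equivalent data frame).
#' @param classification a `probe_classification` from [classify_probes()].
#' @param probe_ids probes present in the methylation matrix; annotation rows
#'   for absent probes are dropped.
#' @return A `gene_probe_map`: named list, one data frame per gene with
#'   columns `probe_id`, `group`, `class`.
#' @export
build_gene_probe_map <- function(annotation, classification, probe_ids) {
  ann <- annotation[annotation$probe_id %in% probe_ids, , drop = FALSE]
  cls <- stats::setNames(classification$class, classification$probe_id)
  ann$class <- unname(cls[ann$probe_id])
  if (anyNA(ann$class))
    stop("annotation references probes missing from the classification")
  ann <- ann[order(ann$gene, ann$probe_id), , drop = FALSE]
  map <- split(ann[c("probe_id", "group", "class")], ann$gene)
  map <- lapply(map, function(d) { rownames(d) <- NULL; d })
  structure(map, class = c("gene_probe_map", class(map)))
}

#' Probes for a gene under a probe-set and region filter
#'
#' Filters the gene's probes first by class (`methylation`, `s_and_c`, or
#' `all` = their union) and then by region. The promoter region is
#' TSS1500 / TSS200 / 5'UTR / 1st exon; the gene body is `Body`; 3'UTR-only
#' probes belong to neither region subset. A probe annotated to the gene
#' under any qualifying group is included once.
#'
#' @param gene gene symbol.
#' @param map a `gene_probe_map`.
#' @param probe_set_mode one of `"methylation"`, `"s_and_c"`, `"all"`.
#' @param region_mode one of `"all"`, `"promoter"`, `"body"`.
#' @return Character vector of probe ids in ascending id order; empty (with
#'   a warning) for a gene absent from the map.
#' @export
probes_for_gene <- function(gene, map,
                            probe_set_mode = c("methylation", "s_and_c", "all"),
                            region_mode = c("all", "promoter", "body")) {
  probe_set_mode <- match.arg(probe_set_mode)
  region_mode <- match.arg(region_mode)
  d <- map[[gene]]
  if (is.null(d)) {
    warning(sprintf("gene '%s' not in probe map", gene))
    return(character())
  }
  if (probe_set_mode != "all") d <- d[d$class == probe_set_mode, , drop = FALSE]
  if (region_mode == "promoter") d <- d[d$group %in% PROMOTER_GROUPS, , drop = FALSE]
  if (region_mode == "body") d <- d[d$group == "Body", , drop = FALSE]
  sort(unique(d$probe_id))
}
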