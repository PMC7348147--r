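## plain-text readers/writers for the pipeline's exchange formats

#' Write a count matrix to a directory
#'
#' Emits `counts.tsv` (genes x samples with a header row of sample ids),
#' `counts.mtx` plus `genes.txt`/`samples.txt` index files,
#' `sample_annotations.tsv` and, when present, `gene_lengths.tsv`.
#'
#' @param cm a [count_matrix()].
#' @param dir output directory.
#' @export
write_count_matrix <- function(cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dt <- data.table::data.table(gene = rownames(cm$counts))
  dt <- cbind(dt, data.table::as.data.table(cm$counts))
  data.table::fwrite(dt, file.path(dir, "counts.tsv"), sep = "\t")
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(cm$counts), file.path(dir, "genes.txt"))
  writeLines(colnames(cm$counts), file.path(dir, "samples.txt"))
  data.table::fwrite(cm$samples, file.path(dir, "sample_annotations.tsv"), sep = "\t")
  if (!is.null(cm$gene_lengths))
    data.table::fwrite(data.frame(gene = names(cm$gene_lengths),
                                  length = as.integer(cm$gene_lengths)),
                       file.path(dir, "gene_lengths.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' Accepts either the TSV (`counts.tsv`) or the MTX triplet.
#'
#' @param dir directory holding the files.
#' @param format `"tsv"` or `"mtx"`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::fread(file.path(dir, "counts.tsv"), sep = "\t")
    genes <- dt$gene
    m <- as.matrix(dt[, -1])
    rownames(m) <- genes
  } else {
    m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
    rownames(m) <- readLines(file.path(dir, "genes.txt"))
    colnames(m) <- readLines(file.path(dir, "samples.txt"))
  }
  ann <- as.data.frame(data.table::fread(file.path(dir, "sample_annotations.tsv")))
  gl_path <- file.path(dir, "gene_lengths.tsv")
  gl <- NULL
  if (file.exists(gl_path)) {
    gld <- data.table::fread(gl_path)
    gl <- stats::setNames(gld$length, gld$gene)
  }
  count_matrix(m, ann, gl)
}

#' Write signatures as long-format TSV
#'
#' Columns: signature_id, tissue, topic, polarity, platform, gene, log2fc.
#'
#' @param sigs list of [signature_fc()].
#' @param path output path.
#' @export
write_signatures <- function(sigs, path) {
  dt <- data.table::rbindlist(lapply(sigs, function(s)
    data.table::data.table(signature_id = s$id, tissue = s$tissue,
                           topic = s$topic, polarity = s$polarity,
                           platform = s$platform, gene = names(s$values),
                           log2fc = unname(s$values))))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read signatures from long-format TSV
#' @param path file written by [write_signatures()].
#' @return list of [signature_fc()].
#' @export
read_signatures <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  lapply(split(dt, by = "signature_id", sorted = FALSE), function(d)
    signature_fc(d$signature_id[1], stats::setNames(d$log2fc, d$gene),
                 tissue = as.character(d$tissue[1]), topic = d$topic[1],
                 polarity = d$polarity[1], platform = d$platform[1]))
}

#' Write a DEG table as TSV
#' @param tab a `deg_table`.
#' @param path output path.
#' @export
write_deg_table <- function(tab, path) {
  data.table::fwrite(data.frame(gene = tab$gene, log2FC = tab$log2fc,
                                PValue = tab$p_value, direction = tab$direction),
                     path, sep = "\t")
  invisible(path)
}

#' Write a DEG summary as JSON
#' @param summ a `deg_summary`.
#' @param path output path.
#' @export
write_deg_summary <- function(summ, path) {
  jsonlite::write_json(list(per_tissue = summ$per_tissue,
                            n_total_degs = summ$n_total_degs,
                            sharing = stats::setNames(as.list(summ$sharing),
                                                      summ$sharing_levels),
                            cosine = as.data.frame(summ$cosine),
                            modules = as.list(summ$modules)),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a sample dendrogram in Newick format
#' @param hc an [stats::hclust] object.
#' @param path output path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Read drug target annotations
#' @param path TSV with columns drug, target, source_db.
#' @return data.frame.
#' @export
read_drug_targets <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("drug", "target", "source_db")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("drug target file missing columns: ", paste(miss, collapse = ", "))
  df$target <- toupper(df$target)
  df
}
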