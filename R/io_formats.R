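#' Read a GMT geneset collection
#'
#' Parses the standard GMT dialect: one geneset per line, tab-separated as
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. Member order is
#' preserved; duplicate members within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (pathway name -> unique genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop(sprintf("malformed GMT line %d: geneset '%s' has no members", i, fields[[1]]))
    }
    nms[[i]] <- fields[[1]]
    sets[[i]] <- genes
  }
  names(sets) <- nms
  sets
}

#' Write a geneset collection in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default non-silent variant classes
#'
#' The standard MAF variant classifications treated as gene-inactivating
#' mutation events. Silent/synonymous and non-coding classes are excluded.
#'
#' @return Character vector of variant classifications.
#' @export
nonsilent_classes_default <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "Splice_Site", "In_Frame_Del", "In_Frame_Ins",
    "Translation_Start_Site", "Nonstop_Mutation")
}

#' Read a MAF-like mutation table into a binary sample x gene matrix
#'
#' Only rows whose \code{variant_classification} is listed in
#' \code{nonsilent_classes} count as mutation events; all other rows are
#' treated as silent (unknown classes trigger a warning). A cell is 1 iff the
#' sample carries at least one non-silent mutation in the gene.
#'
#' @param path TSV with columns \code{sample}, \code{gene},
#'   \code{variant_classification}.
#' @param nonsilent_classes Variant classes counted as mutation events.
#' @param samples,genes Optional identifier universes fixing matrix dimensions
#'   (samples/genes absent from the file get all-zero rows/columns).
#' @return Binary integer matrix, samples in rows, genes in columns.
#' @export
read_mutation_table <- function(path,
                                nonsilent_classes = nonsilent_classes_default(),
                                samples = NULL, genes = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample", "gene", "variant_classification")
  missing <- setdiff(required, colnames(tab))
  if (length(missing) > 0L) {
    stop("mutation table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  known <- c(nonsilent_classes,
             c("Silent", "Synonymous", "3'UTR", "5'UTR", "Intron", "IGR",
               "RNA", "3'Flank", "5'Flank"))
  unknown <- setdiff(unique(tab$variant_classification), known)
  if (length(unknown) > 0L) {
    warning("unlisted variant classification(s) treated as silent: ",
            paste(unknown, collapse = ", "))
  }
  hit <- tab[tab$variant_classification %in% nonsilent_classes, , drop = FALSE]
  samples <- samples %||% sort(unique(tab$sample))
  genes <- genes %||% sort(unique(tab$gene))
  mut <- matrix(0L, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  if (nrow(hit) > 0L) {
    mut[cbind(match(hit$sample, samples), match(hit$gene, genes))] <- 1L
  }
  mut
}

#' Write a numeric matrix as TSV with a leading id column
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param id_name Header of the leading id column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by \code{write_matrix_tsv}
#' @param path Input path.
#' @return Numeric matrix with row names from the leading id column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Assemble a tumor cohort bundle
#'
#' Joins the mutation, expression, and clinical tables to their common sample
#' set (dropped samples are counted in a message), validating the clinical
#' invariants (non-negative times, binary event indicator).
#'
#' @param mutation Binary sample x gene matrix.
#' @param counts Gene x sample raw count matrix (non-negative).
#' @param zscore Gene x sample z-score matrix.
#' @param clinical Data frame with columns \code{sample}, \code{dfs_months},
#'   \code{dfs_event}.
#' @param cancer_type Named character vector (per sample).
#' @return An object of class \code{cohort_bundle}.
#' @export
cohort_bundle <- function(mutation, counts, zscore, clinical, cancer_type) {
  common <- Reduce(intersect, list(rownames(mutation), colnames(counts),
                                   colnames(zscore), clinical$sample,
                                   names(cancer_type)))
  n_all <- length(unique(c(rownames(mutation), colnames(counts),
                           clinical$sample)))
  if (length(common) < n_all) {
    message(sprintf("cohort_bundle: keeping %d samples common to all tables (%d dropped)",
                    length(common), n_all - length(common)))
  }
  clinical <- clinical[match(common, clinical$sample), , drop = FALSE]
  stopifnot(all(clinical$dfs_months >= 0),
            all(clinical$dfs_event %in% c(0, 1)))
  structure(list(
    mutation = mutation[common, , drop = FALSE],
    counts = counts[, common, drop = FALSE],
    zscore = zscore[, common, drop = FALSE],
    clinical = clinical,
    cancer_type = cancer_type[common]
  ), class = "cohort_bundle")
}

#' Assemble a cell-line screen bundle
#'
#' @param mutation Binary cell line x gene matrix.
#' @param essentiality Gene x cell line RNAi essentiality score matrix
#'   (more negative = more essential).
#' @param ic50 Drug x cell line LN-IC50 matrix (lower = more sensitive).
#' @param drug_targets Data frame with columns \code{drug}, \code{target}.
#' @return An object of class \code{screen_bundle}.
#' @export
screen_bundle <- function(mutation, essentiality, ic50, drug_targets) {
  stopifnot(all(mutation %in% c(0L, 1L)))
  structure(list(mutation = mutation, essentiality = essentiality,
                 ic50 = ic50, drug_targets = drug_targets),
            class = "screen_bundle")
}

#' Write a cohort bundle to a directory of TSV files
#' @param cohort A \code{cohort_bundle}.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$mutation, file.path(dir, "mutation.tsv"), "sample")
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"), "gene")
  write_matrix_tsv(cohort$zscore, file.path(dir, "zscore.tsv"), "gene")
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- data.frame(sample = names(cohort$cancer_type),
                   cancer_type = unname(cohort$cancer_type))
  utils::write.table(ct, file.path(dir, "cancer_type.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort bundle from a directory written by \code{write_cohort}
#' @param dir Directory path.
#' @return A \code{cohort_bundle}.
#' @export
read_cohort <- function(dir) {
  mutation <- read_matrix_tsv(file.path(dir, "mutation.tsv"))
  storage.mode(mutation) <- "integer"
  clinical <- utils::read.delim(file.path(dir, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  ct <- utils::read.delim(file.path(dir, "cancer_type.tsv"),
                          stringsAsFactors = FALSE)
  cohort_bundle(
    mutation = mutation,
    counts = read_matrix_tsv(file.path(dir, "counts.tsv")),
    zscore = read_matrix_tsv(file.path(dir, "zscore.tsv")),
    clinical = clinical,
    cancer_type = stats::setNames(ct$cancer_type, ct$sample)
  )
}

#' Write a screen bundle to a directory of TSV files
#' @param screens A \code{screen_bundle}.
#' @param dir Output directory.
#' @export
write_screens <- function(screens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(screens$mutation, file.path(dir, "cell_mutation.tsv"), "cell_line")
  write_matrix_tsv(screens$essentiality, file.path(dir, "essentiality.tsv"), "gene")
  write_matrix_tsv(screens$ic50, file.path(dir, "ln_ic50.tsv"), "drug")
  utils::write.table(screens$drug_targets, file.path(dir, "drug_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a screen bundle from a directory written by \code{write_screens}
#' @param dir Directory path.
#' @return A \code{screen_bundle}.
#' @export
read_screens <- function(dir) {
  mutation <- read_matrix_tsv(file.path(dir, "cell_mutation.tsv"))
  storage.mode(mutation) <- "integer"
  screen_bundle(
    mutation = mutation,
    essentiality = read_matrix_tsv(file.path(dir, "essentiality.tsv")),
    ic50 = read_matrix_tsv(file.path(dir, "ln_ic50.tsv")),
    drug_targets = utils::read.delim(file.path(dir, "drug_targets.tsv"),
                                     stringsAsFactors = FALSE)
  )
}
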