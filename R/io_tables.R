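#' @importFrom stats sd cor pt p.adjust t.test ks.test rnorm rmultinom runif
#' @importFrom utils read.delim write.table head
NULL

KINGDOMS <- c("bacteria", "methanogen", "fungus", "protozoa")
DIETS <- c("CON", "PAS")

#' Construct a taxon-by-sample count table
#'
#' The basic container for one kingdom's community data: an integer matrix of
#' reads (taxa in rows, samples in columns) plus a kingdom label and a
#' semicolon-delimited lineage string per taxon. Protozoa are an exception:
#' they are recorded from optical counts as percentage compositions, so their
#' cells may be non-integer.
#'
#' @param counts numeric matrix, taxa in rows (rownames required), samples in
#'   columns (colnames required). Non-negative; integer unless
#'   `kingdom = "protozoa"`.
#' @param kingdom one of `"bacteria"`, `"methanogen"`, `"fungus"`,
#'   `"protozoa"`.
#' @param lineage optional named character vector (taxon -> lineage string,
#'   ranks separated by `";"`). Defaults to the taxon ID standing in as the
#'   genus.
#' @return an object of class `count_table` with fields `counts`, `kingdom`,
#'   `lineage`, `taxa`, `samples`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("a1_CON", "a1_PAS")))
#' count_table(m, "bacteria")
#' @export
count_table <- function(counts, kingdom, lineage = NULL) {
  kingdom <- match.arg(kingdom, KINGDOMS)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count table needs taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate taxon IDs: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample IDs: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stopf("counts must be numeric and complete")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stopf("negative count at taxon '%s', sample '%s'",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  if (kingdom != "protozoa") {
    if (any(counts != floor(counts))) {
      bad <- which(counts != floor(counts), arr.ind = TRUE)[1, ]
      stopf("non-integer count at taxon '%s', sample '%s'",
            rownames(counts)[bad[1]], colnames(counts)[bad[2]])
    }
    if (max(counts) <= .Machine$integer.max) storage.mode(counts) <- "integer"
  }
  if (is.null(lineage)) {
    lineage <- rownames(counts)
    names(lineage) <- rownames(counts)
  }
  if (!all(rownames(counts) %in% names(lineage)))
    stopf("lineage missing for some taxa")
  structure(
    list(counts = counts, kingdom = kingdom,
         lineage = lineage[rownames(counts)],
         taxa = rownames(counts), samples = colnames(counts)),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s]: %d taxa x %d samples, total %s reads\n",
              x$kingdom, length(x$taxa), length(x$samples),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a count table from a tab-separated file
#'
#' Expected layout: first column `taxon`, optional second column `lineage`,
#' remaining columns one per sample holding integer read counts.
#'
#' @param path file path.
#' @param kingdom kingdom label for the table.
#' @return a validated [count_table()].
#' @export
read_count_table <- function(path, kingdom) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "taxon")
    stopf("malformed header in '%s': first column must be 'taxon'", path)
  lineage <- NULL
  if (ncol(df) >= 2 && names(df)[2] == "lineage") {
    lineage <- df[[2]]
    names(lineage) <- df[[1]]
    df <- df[, -2, drop = FALSE]
  }
  if (ncol(df) < 2) stopf("no sample columns in '%s'", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(df$taxon, colnames(m))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stopf("non-numeric cell at row '%s', column '%s' in '%s'",
          rownames(num)[bad[1]], colnames(num)[bad[2]], path)
  }
  count_table(num, kingdom, lineage)
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]: the round trip reproduces the table
#' exactly. Non-integer (protozoa) values are serialized at 6 significant
#' digits.
#'
#' @param x a [count_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(taxon = x$taxa, lineage = unname(x$lineage),
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- x$counts
  out <- as.data.frame(apply(vals, 2, format_num), check.names = FALSE,
                       stringsAsFactors = FALSE)
  df <- cbind(df, out)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct sample metadata
#'
#' Maps each sample to its animal and diet. The design is a two-period
#' crossover: every animal is sampled once per diet, so paired contrasts are
#' formed within animal. Sample IDs follow the `<animal>_<diet>` convention.
#'
#' @param sample character vector of sample IDs.
#' @param animal character vector of animal IDs.
#' @param diet character vector, each `"CON"` (hay + concentrate) or `"PAS"`
#'   (pasture).
#' @return a `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample, animal, diet) {
  df <- data.frame(sample = as.character(sample),
                   animal = as.character(animal),
                   diet = as.character(diet), stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample))
    stopf("duplicate sample IDs in metadata")
  bad <- setdiff(unique(df$diet), DIETS)
  if (length(bad))
    stopf("unknown diet label(s): %s (expected CON or PAS)",
          paste(bad, collapse = ", "))
  if (anyDuplicated(df[, c("animal", "diet")]))
    stopf("an animal appears more than once within a diet")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Animals sampled under both diets
#' @param metadata a [sample_metadata()] frame.
#' @return character vector of animal IDs with a complete CON/PAS pair.
#' @export
paired_animals <- function(metadata) {
  tab <- table(metadata$animal, metadata$diet)
  rownames(tab)[rowSums(tab[, DIETS, drop = FALSE] > 0) == 2]
}

#' Read sample metadata from CSV
#'
#' Expects columns `sample`, `animal`, `diet`.
#' @param path file path.
#' @return a [sample_metadata()] frame.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, sep = ",", check.names = FALSE,
                   colClasses = "character")
  need <- c("sample", "animal", "diet")
  if (!all(need %in% names(df)))
    stopf("metadata must have columns %s", paste(need, collapse = ", "))
  sample_metadata(df$sample, df$animal, df$diet)
}

#' @rdname read_metadata
#' @param metadata a [sample_metadata()] frame.
#' @export
write_metadata <- function(metadata, path) {
  write.table(as.data.frame(metadata), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Variables of a rumen fermentation profile
#' @return character vector of the per-sample chemistry columns.
#' @export
fermentation_variables <- function() {
  c("pH", "ammonia_N", "total_VFA",
    "acetate", "propionate", "butyrate", "iso_butyrate",
    "valerate", "iso_valerate", "caproate", "iso_caproate",
    "lactate", "DL_lactate_ratio", "protozoa_log")
}

MOLAR_PROPORTIONS <- c("acetate", "propionate", "butyrate", "iso_butyrate",
                       "valerate", "iso_valerate", "caproate", "iso_caproate")

#' Construct / validate a fermentation profile table
#'
#' One row per sample: pH, ammonia nitrogen (mg/L), total VFA (mM), the eight
#' VFA molar proportions (% of total VFA, summing to 100 within rounding),
#' lactate (mM), the D/L lactate ratio, and the protozoal concentration
#' (log10 cells/mL).
#'
#' @param df data.frame with a `sample` column plus the columns of
#'   [fermentation_variables()].
#' @return the validated data.frame, classed `fermentation_profile`.
#' @export
fermentation_profile <- function(df) {
  need <- c("sample", fermentation_variables())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("fermentation table missing column(s): %s",
          paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) stopf("duplicate sample IDs")
  num <- df[, fermentation_variables()]
  if (anyNA(num)) stopf("fermentation table has missing values")
  if (any(df$total_VFA < 0)) stopf("total_VFA must be non-negative")
  props <- as.matrix(df[, MOLAR_PROPORTIONS])
  if (any(props < 0)) stopf("molar proportions must be non-negative")
  s <- rowSums(props)
  bad <- which(s < 95 | s > 105)
  if (length(bad))
    stopf("molar proportions of sample '%s' sum to %.2f (must be in [95, 105])",
          df$sample[bad[1]], s[bad[1]])
  df <- df[, need]
  class(df) <- c("fermentation_profile", "data.frame")
  df
}

#' Read / write a fermentation profile CSV
#' @param path file path.
#' @return a [fermentation_profile()] frame.
#' @export
read_fermentation <- function(path) {
  df <- read.delim(path, sep = ",", check.names = FALSE)
  fermentation_profile(df)
}

#' @rdname read_fermentation
#' @param profile a [fermentation_profile()] frame.
#' @export
write_fermentation <- function(profile, path) {
  out <- as.data.frame(profile)
  for (v in fermentation_variables()) out[[v]] <- format_num(out[[v]])
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that every sample of a count table is described in the metadata
#' @param x a [count_table()].
#' @param metadata a [sample_metadata()] frame.
#' @return `TRUE` invisibly, or an error naming the orphan samples.
#' @export
validate_samples <- function(x, metadata) {
  orphan <- setdiff(x$samples, metadata$sample)
  if (length(orphan))
    stopf("sample(s) present in counts but absent in metadata: %s",
          paste(orphan, collapse = ", "))
  invisible(TRUE)
}

#' Write a co-occurrence network edge list as TSV
#'
#' Columns `source`, `target`, `rho`, `sign`, `p_adj`; rows sorted
#' lexicographically by (source, target) so identical networks diff as
#' identical files.
#'
#' @param network a [build_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "cooccurrence_network"))
  e <- network$edges
  e <- e[order(e$source, e$target), , drop = FALSE]
  out <- data.frame(source = e$source, target = e$target,
                    rho = format_num(e$rho), sign = e$sign,
                    p_adj = format_num(e$p_adj), stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
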