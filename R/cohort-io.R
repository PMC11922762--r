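#' Construct a validated count matrix
#'
#' A `count_matrix` is the pipeline's entry point: a genes x samples matrix
#' of raw, non-negative integer RNA-seq counts tagged with the species it
#' came from and a free-text cohort label.
#'
#' @param values numeric matrix, genes in rows, samples in columns. All
#'   entries must be non-negative integers (integer storage is not required;
#'   `2` and `2.0` are both accepted, `2.5` is not).
#' @param species `"human"` or `"mouse"`.
#' @param cohort free-text cohort tag.
#' @return The matrix with class `count_matrix` and attributes `species`
#'   and `cohort`.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' count_matrix(m, species = "human")
#' @export
count_matrix <- function(values, species = c("human", "mouse"),
                         cohort = "cohort") {
  species <- match.arg(species)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("count matrix must have gene (row) and sample (column) names")
  if (anyDuplicated(gid))
    stop("duplicate gene id(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0 | values != round(values))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop("non-integer or negative count at gene '", gid[i],
         "', sample '", sid[j], "'")
  }
  structure(values, class = c("count_matrix", "matrix", "array"),
            species = species, cohort = cohort)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples [%s, cohort '%s']\n",
              nrow(x), ncol(x), attr(x, "species"), attr(x, "cohort")))
  invisible(x)
}

# keep class/attrs through [ subsetting with both indices
#' @export
`[.count_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, class = class(x), species = attr(x, "species"),
                     cohort = attr(x, "cohort"))
  out
}

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV layout: header row of sample ids, first column gene ids. The
#' MatrixMarket layout is a coordinate `.mtx` file with sidecar row and
#' column id files (`<path>.rownames` / `<path>.colnames`, one id per
#' line); omitted cells are zeros, per the sparse convention.
#'
#' @param path file path (for `format = "mtx"`, the `.mtx` file).
#' @param format `"tsv"` or `"mtx"`.
#' @inheritParams count_matrix
#' @return a [count_matrix()].
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        species = c("human", "mouse"), cohort = "cohort") {
  format <- match.arg(format)
  species <- match.arg(species)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    gid <- as.character(df[[1]])
    if (anyDuplicated(gid))
      stop("duplicate gene id(s) in ", path, ": ",
           paste(unique(gid[duplicated(gid)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- gid
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar id files do not match matrix dimensions for ", path)
    dimnames(m) <- list(rn, cn)
  }
  count_matrix(m, species = species, cohort = cohort)
}

#' Write a count matrix to TSV or MatrixMarket
#'
#' @param x a [count_matrix()] (any named matrix is accepted).
#' @param path output path; for `"mtx"` the sidecar id files
#'   `<path>.rownames` and `<path>.colnames` are written alongside.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE), path)
    writeLines(rownames(x), paste0(path, ".rownames"))
    writeLines(colnames(x), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Read a one-to-one ortholog map
#'
#' Two-column text (human id, mouse id), tab- or whitespace-separated, with
#' an optional header. Any human or mouse id appearing in more than one
#' pair is ambiguous under the one-to-one rule; all pairs involving it are
#' dropped, and the number dropped is reported via `message()`.
#'
#' @param path file path.
#' @return data.frame with columns `human`, `mouse`, class `ortholog_map`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("human", "mouse"),
                          colClasses = "character")
  # tolerate a header line
  if (nrow(df) && (tolower(df$human[1]) %in% c("human", "human_gene_id") ||
                   tolower(df$mouse[1]) %in% c("mouse", "mouse_gene_id")))
    df <- df[-1, , drop = FALSE]
  ortholog_map(df$human, df$mouse)
}

#' Construct a one-to-one ortholog map
#'
#' @param human,mouse character vectors of paired gene ids.
#' @return data.frame with columns `human`, `mouse`, class `ortholog_map`.
#' @export
ortholog_map <- function(human, mouse) {
  stopifnot(length(human) == length(mouse))
  df <- unique(data.frame(human = as.character(human),
                          mouse = as.character(mouse),
                          stringsAsFactors = FALSE))
  amb <- df$human %in% df$human[duplicated(df$human)] |
         df$mouse %in% df$mouse[duplicated(df$mouse)]
  if (any(amb))
    message(sum(amb), " pair(s) dropped as ambiguous under the one-to-one rule")
  df <- df[!amb, , drop = FALSE]
  if (nrow(df) == 0)
    stop("no one-to-one ortholog pairs remain after filtering")
  rownames(df) <- NULL
  class(df) <- c("ortholog_map", "data.frame")
  df
}

#' Write an ortholog map as two-column TSV
#' @param omap an [ortholog_map()].
#' @param path output path.
#' @export
write_ortholog_map <- function(omap, path) {
  utils::write.table(as.data.frame(omap), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("human", "mouse"))
  invisible(path)
}

#' Harmonize human and mouse matrices onto the shared ortholog axis
#'
#' Both matrices are restricted to ortholog pairs present in both, and the
#' mouse rows are renamed to their human partner id so every downstream
#' stage operates in a single (human) gene namespace. Row order is
#' lexicographic by human gene id, identical in both outputs; the operation
#' is idempotent.
#'
#' @param human,mouse genes x samples matrices ([count_matrix()] or
#'   expression matrices); `human` rows are human gene ids, `mouse` rows
#'   mouse gene ids (or already-translated human ids).
#' @param omap an [ortholog_map()].
#' @return list with elements `human` and `mouse`, row-aligned.
#' @export
harmonize <- function(human, mouse, omap) {
  stopifnot(inherits(omap, "ortholog_map"))
  # accept mouse matrices already carrying human ids (idempotence)
  mmap <- omap$mouse
  names(mmap) <- omap$human
  mrows <- rownames(mouse)
  mouse_as_human <- ifelse(mrows %in% omap$mouse,
                           omap$human[match(mrows, omap$mouse)], mrows)
  shared <- intersect(intersect(rownames(human), omap$human), mouse_as_human)
  if (length(shared) == 0) stop("no shared orthologs between the two matrices")
  shared <- sort(shared)
  h <- human[shared, , drop = FALSE]
  m <- mouse[match(shared, mouse_as_human), , drop = FALSE]
  rownames(m) <- shared
  list(human = h, mouse = m)
}

#' Read a GMT gene-set collection
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. The
#' description field is ignored; duplicate genes within a set are
#' deduplicated. Duplicate set names or empty gene lists are errors.
#'
#' @param path file path.
#' @return named list of character vectors, class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  empty <- lengths(sets) == 0
  if (any(empty))
    stop("gene set(s) with empty gene list: ",
         paste(nm[empty], collapse = ", "))
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors of gene ids.
#' @return the list with class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  structure(sets, class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection as GMT
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Read per-sample metadata TSV
#'
#' Expects a `sample_id` column (unique); other columns are free-form
#' (species, cohort, mutation flags, histology, survival `time`/`event`).
#' Missing values are permitted everywhere except `sample_id`.
#'
#' @param path file path.
#' @return data.frame keyed by `sample_id`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if ("event" %in% names(df)) {
    ev <- df$event[!is.na(df$event)]
    if (!all(ev %in% c(0, 1))) stop("event indicator must be 0/1")
  }
  df
}
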