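#' Occurrence tables
#'
#' An `occurrence_table` is a binary genus x sample matrix with unique row
#' (genus) and column (sample) labels. It is the central data structure from
#' which co-occurrence networks are built.
#'
#' @param X binary matrix (0/1) with genera as rows and samples as columns;
#'   must carry unique rownames and colnames.
#' @return An object of class `occurrence_table` (a 0/1 integer matrix with
#'   dimnames).
#' @export
occurrence_table <- function(X) {
  X <- as.matrix(X)
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("occurrence table needs genus rownames and sample colnames")
  if (anyDuplicated(rownames(X)))
    stop("duplicate genus labels: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  if (anyDuplicated(colnames(X)))
    stop("duplicate sample labels: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  bad <- which(!(X %in% c(0L, 1L)))
  if (length(bad)) {
    bad1 <- arrayInd(bad[1], dim(X))
    stop(sprintf("non-binary value %s at (%s,%s)", format(X[bad[1]]),
                 rownames(X)[bad1[1]], colnames(X)[bad1[2]]))
  }
  storage.mode(X) <- "integer"
  class(X) <- c("occurrence_table", class(X))
  X
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("occurrence_table: %d genera x %d samples, fill %.3f\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Read an occurrence table and its sample annotation
#'
#' The occurrence table is a TSV with a header row of sample identifiers and
#' the genus identifier in the first column; cells are 0/1. The annotation
#' file is a TSV with columns `sample_id`, `env_type` and `env_subtype`
#' (subtype nested within type). Samples present in the table but absent from
#' the annotation are flagged with a warning; downstream network construction
#' ignores them.
#'
#' @param path occurrence TSV path.
#' @param annotation_path annotation TSV path, or `NULL` to skip.
#' @return A list with elements `table` (an [occurrence_table()]) and
#'   `annotation` (data frame or `NULL`).
#' @export
read_occurrence_table <- function(path, annotation_path = NULL) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genera <- as.character(raw[[1]])
  M <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(M) <- "double")
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at (%s,%s)", genera[bad[1]],
                 colnames(M)[bad[2]]))
  }
  nb <- which(!(M %in% c(0, 1)))
  if (length(nb)) {
    bad <- arrayInd(nb[1], dim(M))
    stop(sprintf("non-binary cell at (%s,%s)", genera[bad[1]],
                 colnames(M)[bad[2]]))
  }
  rownames(M) <- genera
  tab <- occurrence_table(M)
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- read_sample_annotation(annotation_path)
    missing <- setdiff(colnames(tab), ann$sample_id)
    if (length(missing))
      warning(length(missing), " samples lack annotation: ",
              paste(utils::head(missing, 5), collapse = ", "),
              if (length(missing) > 5) ", ..." else "")
  }
  list(table = tab, annotation = ann)
}

#' @rdname read_occurrence_table
#' @export
read_sample_annotation <- function(annotation_path) {
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "env_type", "env_subtype")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation")
  sub2type <- tapply(ann$env_type, ann$env_subtype,
                     function(v) length(unique(v)))
  if (any(sub2type > 1))
    stop("env_subtype not nested within env_type: ",
         paste(names(sub2type)[sub2type > 1], collapse = ", "))
  ann[, need]
}

#' Write an occurrence table (and optionally its annotation) as TSV
#'
#' @param table an [occurrence_table()].
#' @param path output TSV path.
#' @param annotation optional annotation data frame.
#' @param annotation_path output path for the annotation.
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(table, path, annotation = NULL,
                                   annotation_path = NULL) {
  df <- data.frame(genus = rownames(table), unclass(table),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation) && !is.null(annotation_path))
    write.table(annotation, annotation_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Filter sparse genera and samples to a joint fixed point
#'
#' Removes genera observed in fewer than `min_samples_per_genus` samples and
#' samples containing fewer than `min_genera_per_sample` genera. Because
#' removing one can invalidate the other, filtering is by default iterated
#' until both constraints hold simultaneously; row and column order is
#' preserved.
#'
#' @param table an [occurrence_table()].
#' @param min_genera_per_sample minimum genera a sample must contain (>= 1).
#' @param min_samples_per_genus minimum samples a genus must occur in (>= 1).
#' @param iterate iterate to the joint fixed point (default) or apply a
#'   single simultaneous pass.
#' @return The filtered [occurrence_table()].
#' @export
filter_occurrence_table <- function(table, min_genera_per_sample = 5,
                                    min_samples_per_genus = 5,
                                    iterate = TRUE) {
  stopifnot(min_genera_per_sample >= 1, min_samples_per_genus >= 1)
  X <- table
  repeat {
    keep_g <- rowSums(X) >= min_samples_per_genus
    keep_s <- colSums(X) >= min_genera_per_sample
    if (!any(keep_g) || !any(keep_s))
      stop("empty after filtering")
    done <- all(keep_g) && all(keep_s)
    X <- X[keep_g, keep_s, drop = FALSE]
    if (done || !iterate) break
  }
  occurrence_table(unclass(X))
}

#' Genus-level core pathway profiles
#'
#' A pathway belongs to the core genome of a genus when it is predicted in
#' every available genome of that genus; the core profile is therefore the
#' intersection of the genus's genome pathway sets.
#'
#' @param genomes data frame with columns `genome_id`, `genus`, `pathway`
#'   (one row per genome/pathway incidence).
#' @param genus genus label, or `NULL` to return profiles for all genera.
#' @return For a single genus, the character vector of core pathways. For
#'   `genus = NULL`, a named list of core pathway vectors (a profile set
#'   usable by [summarize_assemblage()]).
#' @export
core_pathways <- function(genomes, genus = NULL) {
  stopifnot(all(c("genome_id", "genus", "pathway") %in% names(genomes)))
  one <- function(g) {
    sub <- genomes[genomes$genus == g, , drop = FALSE]
    if (nrow(sub) == 0) stop("no genomes for genus ", g)
    sets <- split(sub$pathway, sub$genome_id)
    sort(Reduce(intersect, sets))
  }
  if (!is.null(genus)) return(one(genus))
  gg <- unique(genomes$genus)
  setNames(lapply(gg, one), gg)
}

#' Read a genome x pathway incidence table
#'
#' TSV with columns `genome_id`, `genus`, `pathway` and optionally
#' `pathway_class` (a flat MetaCyc-style class label per pathway).
#'
#' @param path TSV path.
#' @return Data frame of incidences.
#' @export
read_genome_pathways <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "genus", "pathway")
  if (!all(need %in% names(df)))
    stop("pathway table must have columns: ", paste(need, collapse = ", "))
  g2g <- tapply(df$genus, df$genome_id, function(v) length(unique(v)))
  if (any(g2g > 1))
    stop("genomes mapping to multiple genera: ",
         paste(names(g2g)[g2g > 1], collapse = ", "))
  df
}

#' Read a square distance matrix
#'
#' Square TSV (header row + first column of labels). Distances are validated
#' to be symmetric, non-negative, with a zero diagonal.
#'
#' @param path TSV path.
#' @return A symmetric numeric matrix with matching dimnames.
#' @export
read_distance_matrix <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(raw[[1]])
  D <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(D) <- "double"
  rownames(D) <- labs
  validate_distance_matrix(D)
}

validate_distance_matrix <- function(D) {
  if (!isTRUE(all.equal(rownames(D), colnames(D))))
    stop("distance matrix labels mismatch between rows and columns")
  if (any(D < 0)) stop("negative distances")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("nonzero diagonal")
  D
}

#' Aggregate a species-level distance matrix to genus level
#'
#' The distance between two genera is the median of the distances between all
#' cross pairs of member species. The diagonal is forced to zero.
#'
#' @param species_matrix symmetric species x species distance matrix
#'   (substitutions/site).
#' @param species_to_genus named character vector mapping species label to
#'   genus label.
#' @return Symmetric genus x genus distance matrix.
#' @export
genus_distances <- function(species_matrix, species_to_genus) {
  D <- validate_distance_matrix(species_matrix)
  sp <- rownames(D)
  missing <- setdiff(sp, names(species_to_genus))
  if (length(missing))
    stop("species without genus mapping: ", paste(missing, collapse = ", "))
  absent <- setdiff(names(species_to_genus), sp)
  if (length(absent))
    stop("species absent from matrix: ", paste(absent, collapse = ", "))
  gmap <- species_to_genus[sp]
  genera <- unique(unname(gmap))
  G <- matrix(0, length(genera), length(genera),
              dimnames = list(genera, genera))
  idx <- split(seq_along(sp), gmap)
  for (i in seq_along(genera)) {
    for (j in seq_len(i - 1L)) {
      d <- D[idx[[genera[i]]], idx[[genera[j]]], drop = FALSE]
      G[i, j] <- G[j, i] <- median(d)
    }
  }
  G
}

#' Read an amino-acid biosynthetic cost table
#'
#' TSV with columns `amino_acid` and `cost` (positive, biosynthetic cost
#' units such as high-energy phosphate bonds per molecule).
#'
#' @param path TSV path.
#' @return Data frame with `amino_acid` and `cost`.
#' @export
read_aa_costs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("amino_acid", "cost") %in% names(df)))
    stop("cost table must have columns amino_acid, cost")
  if (any(df$cost <= 0)) stop("costs must be positive")
  if (nrow(df) > 20) stop("more than 20 amino acids")
  df
}
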