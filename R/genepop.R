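#' Diploid microsatellite genotype table
#'
#' Allele sizes (repeat units) per individual and locus. The allele pair is
#' unordered and stored sorted (`a1 <= a2`); a missing genotype is encoded as
#' the pair `(0, 0)` only — a half-scored genotype is normalized to missing.
#'
#' @param individual_ids character vector of individual identifiers.
#' @param locus_names unique locus names.
#' @param a1,a2 integer matrices (`n x n_loci`) of allele sizes, 0 = missing.
#' @param pop_labels population label per individual.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(individual_ids, locus_names, a1, a2, pop_labels) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(individual_ids)
  if (anyDuplicated(locus_names)) stop("duplicate locus names")
  if (!all(dim(a1) == c(n, length(locus_names))) || !all(dim(a1) == dim(a2)))
    stop("allele matrices must be n_individuals x n_loci")
  if (any(a1 < 0) || any(a2 < 0)) stop("negative allele sizes")
  half <- xor(a1 == 0L, a2 == 0L)
  a1[half] <- 0L; a2[half] <- 0L
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  pop_labels <- rep_len(as.character(pop_labels), n)
  dimnames(a1) <- dimnames(a2) <- list(individual_ids, locus_names)
  structure(list(individual_ids = as.character(individual_ids),
                 locus_names = as.character(locus_names),
                 a1 = a1, a2 = a2, pop_labels = pop_labels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individual_ids), "individuals x",
      length(x$locus_names), "loci,", length(unique(x$pop_labels)),
      "population(s);", sprintf("%.1f%%", 100 * mean(x$a1 == 0L)),
      "missing genotypes\n")
  invisible(x)
}

#' Populations of a genotype matrix, in first-appearance order
#' @param G a [genotype_matrix()].
#' @return character vector of population labels.
#' @export
populations <- function(G) unique(G$pop_labels)

#' Read a GenePop file (3-digit diploid coding)
#'
#' Parses the GenePop dialect with 3-digit per-allele coding (`"123145"` is
#' the genotype 123/145); `"000000"` is missing. `Pop` separator lines define
#' populations, labelled by the id of their first individual's line or
#' `popN` in order of appearance. The 2-digit dialect is rejected.
#'
#' @param path path to a GenePop file.
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("GenePop file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  if (length(lines) < 2) stop("not a GenePop file (too short): ", path)
  body <- lines[-1]  # first line is a title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found: ", path)
  loci <- trimws(unlist(strsplit(body[seq_len(first_pop - 1)], ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names before first 'Pop'")
  ids <- character(0); pops <- character(0)
  rows1 <- list(); rows2 <- list()
  pop_i <- 0L
  for (ln in body[seq(first_pop, length(body))]) {
    if (toupper(trimws(ln)) == "POP") {
      pop_i <- pop_i + 1L
      next
    }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed GenePop line (no comma): ", ln)
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(gts) != length(loci))
      stop("individual ", id, " has ", length(gts), " genotypes for ",
           length(loci), " loci")
    w <- nchar(gts)
    if (any(w == 4L))
      stop("2-digit GenePop coding detected for individual ", id,
           "; only the 3-digit dialect (6 characters per genotype) is supported")
    if (any(w != 6L))
      stop("genotype string of odd width for individual ", id, ": ",
           gts[which(w != 6L)[1]])
    ids <- c(ids, id)
    pops <- c(pops, paste0("pop", pop_i))
    rows1[[length(rows1) + 1L]] <- as.integer(substr(gts, 1, 3))
    rows2[[length(rows2) + 1L]] <- as.integer(substr(gts, 4, 6))
  }
  if (pop_i > length(unique(pops)))
    warning("empty Pop block(s) in ", path, " (retained)")
  genotype_matrix(ids, loci, do.call(rbind, rows1), do.call(rbind, rows2), pops)
}

#' Write a genotype matrix as a GenePop file
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @param title title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(G, path, title = "chukardemog genotypes") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(G$locus_names, con)
  for (p in populations(G)) {
    writeLines("Pop", con)
    for (i in which(G$pop_labels == p)) {
      gt <- sprintf("%03d%03d", G$a1[i, ], G$a2[i, ])
      writeLines(paste0(G$individual_ids[i], " , ", paste(gt, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a population map (id, name, lon, lat)
#'
#' @param path CSV file with columns `id`, `name`, `lon`, `lat` (decimal
#'   degrees). An empty table is allowed.
#' @return A data frame of class `population_map`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("population map not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("population map must have columns ", paste(need, collapse = ", "))
  population_map(df$id, df$name, df$lon, df$lat)
}

#' Construct a population map
#' @param id unique population ids.
#' @param name population names.
#' @param lon,lat coordinates in decimal degrees.
#' @return A data frame of class `population_map`.
#' @export
population_map <- function(id, name = id, lon = numeric(0), lat = numeric(0)) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate population ids")
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  if (length(id) && (any(!is.finite(lon)) || any(!is.finite(lat))))
    stop("unparsable or non-finite coordinate in population map")
  if (any(abs(lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 180)) stop("longitude outside [-180, 180]")
  structure(data.frame(id = id, name = as.character(name), lon = lon, lat = lat,
                       stringsAsFactors = FALSE),
            class = c("population_map", "data.frame"))
}

#' Write a population map to CSV
#' @param popmap a [population_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  write.csv(as.data.frame(popmap), path, row.names = FALSE)
  invisible(path)
}
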