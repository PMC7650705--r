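#' @include AllClasses.R
NULL

#' Read a text PLINK ped/map pair into a GenotypePanel
#'
#' Standard 6-column ped (family, individual, father, mother, sex,
#' phenotype) followed by two allele columns per marker, with `0 0` for a
#' missing call; 4-column map (chromosome, id, cM, bp, 1-based positions).
#' Codes count the in-sample minor allele per marker; at an exact 50/50
#' tie the lexicographically later allele label is counted, which matches
#' the writer's orientation so that write-then-read round-trips.
#'
#' @param pedPath,mapPath file paths.
#' @return a [GenotypePanel-class].
#' @export
readPlinkText <- function(pedPath, mapPath) {
  mapRaw <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mapRaw) != 4)
    stop("readPlinkText: map file must have 4 columns", call. = FALSE)
  names(mapRaw) <- c("chrom", "id", "cm", "pos")
  m <- nrow(mapRaw)
  pedLines <- readLines(pedPath)
  pedLines <- pedLines[nzchar(trimws(pedLines))]
  fields <- strsplit(trimws(pedLines), "[ \t]+")
  nf <- lengths(fields)
  expected <- 6 + 2 * m
  bad <- which(nf != expected)
  if (length(bad))
    stop(sprintf(
      "readPlinkText: ped line %d has %d fields, expected %d (map lists %d markers)",
      bad[1], nf[bad[1]], expected, m), call. = FALSE)
  ped <- do.call(rbind, fields)
  ids <- ped[, 2]
  n <- nrow(ped)
  a1 <- ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- ped[, 6 + 2 * seq_len(m), drop = FALSE]

  geno <- matrix(NA_integer_, n, m, dimnames = list(ids, mapRaw$id))
  alleleA <- alleleB <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    lab <- sort(unique(obs))
    if (length(lab) > 2)
      stop(sprintf("readPlinkText: marker %s has more than two alleles",
                   mapRaw$id[j]), call. = FALSE)
    if (length(lab) <= 1) {
      # monomorphic (or all-missing): minor allele is degenerate, code 0
      geno[!miss, j] <- 0L
      alleleA[j] <- if (length(lab)) lab else "A"
      alleleB[j] <- alleleA[j]
      next
    }
    cnt <- c(sum(obs == lab[1]), sum(obs == lab[2]))
    # count the minor allele; on a tie count the later-sorting label
    minor <- if (cnt[2] <= cnt[1]) lab[2] else lab[1]
    major <- if (identical(minor, lab[2])) lab[1] else lab[2]
    geno[!miss, j] <- as.integer(x1[!miss] == minor) +
      as.integer(x2[!miss] == minor)
    alleleA[j] <- major; alleleB[j] <- minor
  }
  map <- data.frame(chrom = mapRaw$chrom, id = mapRaw$id, pos = mapRaw$pos,
                    alleleA = alleleA, alleleB = alleleB,
                    stringsAsFactors = FALSE)
  new("GenotypePanel", geno = geno, map = map)
}

#' Write a GenotypePanel as text PLINK ped/map
#'
#' Codes are written as counts of `alleleB` (so 0 -> `A A`, 1 -> `A B`,
#' 2 -> `B B`, `NA` -> `0 0`), with 1-based bp positions in the map.
#'
#' @param panel a [GenotypePanel-class].
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return the two file paths, invisibly.
#' @export
writePlinkText <- function(panel, prefix) {
  stopifnot(is(panel, "GenotypePanel"))
  g <- genoMatrix(panel)
  map <- markerMap(panel)
  mapPath <- paste0(prefix, ".map")
  pedPath <- paste0(prefix, ".ped")
  write.table(data.frame(map$chrom, map$id, 0, map$pos),
              mapPath, row.names = FALSE, col.names = FALSE, quote = FALSE)
  n <- nrow(g); m <- ncol(g)
  lines <- character(n)
  for (i in seq_len(n)) {
    code <- g[i, ]
    x1 <- ifelse(is.na(code), "0", ifelse(code >= 1, map$alleleB, map$alleleA))
    x2 <- ifelse(is.na(code), "0", ifelse(code == 2, map$alleleB, map$alleleA))
    al <- character(2 * m)
    al[c(TRUE, FALSE)] <- x1
    al[c(FALSE, TRUE)] <- x2
    lines[i] <- paste(c(rownames(g)[i], rownames(g)[i], 0, 0, 0, -9, al),
                      collapse = " ")
  }
  writeLines(lines, pedPath)
  invisible(c(ped = pedPath, map = mapPath))
}

#' Phenotype table IO
#'
#' CSV with columns `animal_id`, `trait`, `stage`, `value`.
#'
#' @param x phenotype `data.frame` (for writing).
#' @param path file path.
#' @return `readPhenotypes`: the `data.frame`; `writePhenotypes`: `path`,
#'   invisibly.
#' @export
readPhenotypes <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "trait", "stage", "value")
  if (!all(need %in% names(d)))
    stop("readPhenotypes: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' @rdname readPhenotypes
#' @export
writePhenotypes <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' GRM IO as a dense CSV matrix with animal ids
#'
#' @param grm a [GRM-class] (for writing).
#' @param path file path.
#' @return `readGRM`: a [GRM-class] (frequencies are not stored in the CSV
#'   and come back empty; blend weight is carried in a header comment);
#'   `writeGRM`: `path`, invisibly.
#' @export
writeGRM <- function(grm, path) {
  stopifnot(is(grm, "GRM"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# blend %.17g", grm@blend), con)
  write.csv(data.frame(id = rownames(grmMatrix(grm)), grmMatrix(grm),
                       check.names = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGRM
#' @export
readGRM <- function(path) {
  first <- readLines(path, n = 1)
  blend <- if (startsWith(first, "# blend"))
    as.numeric(sub("# blend ", "", first)) else 0
  d <- read.csv(path, comment.char = "#", check.names = FALSE)
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d$id
  colnames(mat) <- d$id
  storage.mode(mat) <- "double"
  new("GRM", mat = mat, freq = numeric(0), blend = blend)
}
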