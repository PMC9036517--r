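#' Bead frame container
#'
#' One snapshot of labelled coarse-grained bead positions. Stored as a
#' data frame with columns `x`, `y`, `z` (nm), `species` (one of
#' `PC_head`, `PIP2_head`, `glycerol`, `tail`, `protein`, `wafer`),
#' `leaflet` (`top`, `bottom` or `none`) and `residue` (1-based protein
#' residue index, `NA` for non-protein beads), with the box vectors and
#' frame time carried as attributes.
#'
#' @param x,y,z numeric bead coordinates in nm.
#' @param species per-bead species label.
#' @param leaflet per-bead leaflet label (`none` for protein/wafer beads).
#' @param residue per-bead protein residue index (`NA` otherwise).
#' @param box numeric length-3 box vectors (nm).
#' @param time frame index.
#' @return an object of classes `bead_frame` and `data.frame`.
#' @export
bead_frame <- function(x, y, z, species,
                       leaflet = rep("none", length(x)),
                       residue = rep(NA_integer_, length(x)),
                       box, time = 0L) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   species = as.character(species),
                   leaflet = as.character(leaflet),
                   residue = as.integer(residue))
  attr(df, "box") <- as.numeric(box)
  attr(df, "time") <- as.integer(time)
  class(df) <- c("bead_frame", "data.frame")
  validate_bead_frame(df)
}

bead_species_levels <- function() {
  c("PC_head", "PIP2_head", "glycerol", "tail", "protein", "wafer")
}

validate_bead_frame <- function(frame) {
  box <- attr(frame, "box")
  if (is.null(box) || length(box) != 3)
    stopf("bead_frame needs a length-3 box attribute")
  n <- nrow(frame)
  if (length(frame$species) != n)
    stopf("species and positions must have equal length")
  bad <- setdiff(unique(frame$species), bead_species_levels())
  if (length(bad)) stopf("unknown species: %s", paste(bad, collapse = ", "))
  pos <- as.matrix(frame[, c("x", "y", "z")])
  if (any(!is.finite(pos))) stopf("non-finite bead positions")
  out <- pos < 0 | pos > rep(box, each = n)
  if (any(out))
    stopf("%d bead coordinate(s) outside the box after wrapping", sum(out))
  if (any(frame$species == "PIP2_head" & frame$leaflet != "top"))
    stopf("PIP2_head beads must carry leaflet = top")
  frame
}

#' @export
print.bead_frame <- function(x, ...) {
  box <- attr(x, "box")
  cat(sprintf("bead_frame: %d beads, box %.1f x %.1f x %.1f nm, t = %d\n",
              nrow(x), box[1], box[2], box[3], attr(x, "time")))
  print(table(x$species))
  invisible(x)
}

# residue-name / atom-name mapping used by the GRO writer and reader
.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL", X = "UNK")

gro_names_for <- function(frame, sequence = NULL) {
  n <- nrow(frame)
  resname <- character(n); atom <- character(n); resid <- integer(n)
  is_lip <- frame$species %in% c("PC_head", "PIP2_head", "glycerol", "tail")
  # lipids are grouped into residues by contiguous runs starting at a head
  head_row <- frame$species %in% c("PC_head", "PIP2_head")
  lip_res <- cumsum(head_row)
  atom[frame$species %in% c("PC_head", "PIP2_head")] <- "PO4"
  atom[frame$species == "glycerol"] <- "GL1"
  atom[frame$species == "wafer"] <- "Q0"
  atom[frame$species == "protein"] <- "BB"
  # tail beads within one lipid get C1A, C2A, ...
  if (any(frame$species == "tail")) {
    tl <- which(frame$species == "tail")
    idx <- stats::ave(seq_along(tl), lip_res[tl], FUN = seq_along)
    atom[tl] <- sprintf("C%dA", idx)
  }
  resname[is_lip] <- "DOPC"
  if (any(is_lip)) {
    pip2_res <- lip_res[frame$species == "PIP2_head"]
    resname[is_lip & lip_res %in% pip2_res] <- "POP2"
  }
  resname[frame$species == "wafer"] <- "WAF"
  if (any(frame$species == "protein")) {
    ri <- frame$residue[frame$species == "protein"]
    code <- if (!is.null(sequence)) sequence[ri] else rep("X", length(ri))
    code[is.na(code)] <- "X"
    resname[frame$species == "protein"] <- unname(.aa3[code])
  }
  resid[is_lip] <- lip_res[is_lip]
  n_lip_res <- if (any(is_lip)) max(lip_res[is_lip]) else 0L
  other <- which(!is_lip)
  if (length(other)) {
    pr <- frame$species[other] == "protein"
    resid[other[pr]] <- n_lip_res + frame$residue[other[pr]]
    resid[other[!pr]] <- n_lip_res +
      max(0L, frame$residue[other[pr]], na.rm = TRUE) + seq_len(sum(!pr))
  }
  list(resid = resid, resname = resname, atom = atom)
}

#' Write and read GRO coordinate files
#'
#' Fixed-width Gromacs GRO format, coordinates in nm with 3-decimal
#' precision, box vectors on the final line. `read_gro()` maps residue and
#' atom names back to bead species (`DOPC/PO4` -> `PC_head`, `POP2/PO4` ->
#' `PIP2_head`, `GL1` -> `glycerol`, `C?A` -> `tail`, amino-acid residue
#' names -> `protein`) and infers the leaflet of each lipid from its
#' headgroup height relative to the median headgroup height, which
#' separates the leaflets whenever the pore depth is smaller than the
#' bilayer separation (true of the bundled geometry).
#'
#' @param frame a [bead_frame()].
#' @param path file path.
#' @param title title line to write.
#' @param sequence optional one-letter residue codes used to name protein
#'   residues.
#' @return `write_gro()` returns `path` invisibly; `read_gro()` a
#'   `bead_frame`.
#' @export
write_gro <- function(frame, path, title = "curvsense synthetic frame",
                      sequence = NULL) {
  stopifnot(inherits(frame, "bead_frame"))
  nm <- gro_names_for(frame, sequence)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stopf("cannot open '%s' for writing", path)
  on.exit(close(con))
  writeLines(title, con)
  writeLines(sprintf("%5d", nrow(frame)), con)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   nm$resid %% 100000, nm$resname, nm$atom,
                   seq_len(nrow(frame)) %% 100000,
                   frame$x, frame$y, frame$z)
  writeLines(lines, con)
  box <- attr(frame, "box")
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  invisible(path)
}

#' @rdname write_gro
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stopf("GRO file not found: %s", path)
  ln <- readLines(path)
  if (length(ln) < 3) stopf("truncated GRO file: %s", path)
  n <- suppressWarnings(as.integer(trimws(ln[2])))
  if (is.na(n) || length(ln) < n + 3)
    stopf("GRO atom count (%s) does not match file length", trimws(ln[2]))
  at <- ln[3:(n + 2)]
  resid <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  atom <- trimws(substr(at, 11, 15))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  if (any(is.na(c(x, y, z))))
    stopf("non-numeric coordinates in %s (first bad atom line %d)",
          path, which(is.na(x + y + z))[1])
  box <- as.numeric(strsplit(trimws(ln[n + 3]), "\\s+")[[1]])[1:3]
  species <- rep(NA_character_, n)
  species[atom == "PO4" & resname == "DOPC"] <- "PC_head"
  species[atom == "PO4" & resname == "POP2"] <- "PIP2_head"
  species[atom == "GL1"] <- "glycerol"
  species[grepl("^C[0-9]+A$", atom)] <- "tail"
  species[resname == "WAF"] <- "wafer"
  species[resname %in% .aa3] <- "protein"
  if (anyNA(species))
    stopf("unrecognized atom/residue names in %s", path)
  leaflet <- rep("none", n)
  residue <- rep(NA_integer_, n)
  is_lip <- species %in% c("PC_head", "PIP2_head", "glycerol", "tail")
  if (any(is_lip)) {
    # leaflet from intramolecular geometry: a top-leaflet lipid has its
    # tail beads below the headgroup, a bottom-leaflet lipid above
    heads <- species %in% c("PC_head", "PIP2_head")
    head_z <- setNames(z[heads], resid[heads])
    tail_rows <- species == "tail"
    tail_mean <- tapply(z[tail_rows], resid[tail_rows], mean)
    key <- as.character(resid[is_lip])
    lf <- ifelse(head_z[key] > tail_mean[key], "top", "bottom")
    # lipids without tail beads: fall back to the global median head height
    miss <- is.na(lf)
    if (any(miss)) lf[miss] <- ifelse(head_z[key[miss]] >
                                        median(z[heads]), "top", "bottom")
    leaflet[is_lip] <- lf
  }
  if (any(species == "protein")) {
    pr <- which(species == "protein")
    residue[pr] <- resid[pr] - min(resid[pr]) + 1L
  }
  bead_frame(x, y, z, species, leaflet, residue, box = box, time = 0L)
}
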