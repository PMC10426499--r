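#' Write a 3D volume as a text-encoded NRRD file
#'
#' Minimal NRRD writer (NRRD0004, `encoding: ascii`) sufficient for the
#' phantom/preprocess external interfaces. Data are written in NRRD's native
#' fastest-first axis order, which matches R's column-major layout.
#'
#' @param arr 3D numeric or logical array.
#' @param path output file path (conventionally `.nrrd`).
#' @param spacing numeric length-3 voxel spacing in mm.
#' @export
write_nrrd <- function(arr, path, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(arr)) == 3L)
  type <- if (is.logical(arr) || is.integer(arr)) "int" else "double"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    paste0("spacings: ", paste(format(spacing, digits = 17), collapse = " ")),
    "encoding: ascii",
    ""), con)
  vals <- if (type == "int") as.integer(arr) else as.numeric(arr)
  txt <- if (type == "int") format(vals) else sprintf("%.17g", vals)
  writeLines(paste(txt, collapse = " "), con)
  invisible(path)
}

#' Read a text-encoded NRRD file written by [write_nrrd()]
#'
#' @param path file path.
#' @return list with `data` (3D array) and `spacing`.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) stop("not an NRRD file: ", path)
  blank <- which(lines == "")[1]
  hdr <- lines[2:(blank - 1)]
  get_field <- function(name) {
    ln <- hdr[startsWith(hdr, paste0(name, ":"))]
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^", name, ":"), "", ln[1]))
  }
  enc <- get_field("encoding")
  if (!enc %in% c("ascii", "txt", "text"))
    stop("only text-encoded NRRD is supported (encoding: ", enc, ")")
  sizes <- as.integer(strsplit(get_field("sizes"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get_field("spacings"), "\\s+")[[1]])
  type <- get_field("type")
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               what = if (type %in% c("int", "short", "uchar")) integer() else double(),
               quiet = TRUE)
  if (length(vals) != prod(sizes)) stop("NRRD data length mismatch")
  list(data = array(vals, dim = sizes), spacing = spacing)
}

#' Write a phantom cohort to disk
#'
#' Writes one image/mask NRRD pair per subject plus a `labels.csv`
#' (`subject_id,label`) in `dir`.
#'
#' @param cohort list of subjects as returned by [generate_cohort()].
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labs <- data.frame(subject_id = character(0), label = integer(0))
  for (s in cohort) {
    write_nrrd(s$volume$intensities, file.path(dir, paste0(s$id, "_image.nrrd")),
               s$volume$spacing)
    write_nrrd(s$volume$mask, file.path(dir, paste0(s$id, "_mask.nrrd")),
               s$volume$spacing)
    labs <- rbind(labs, data.frame(subject_id = s$id, label = s$label))
  }
  write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir directory containing `*_image.nrrd`, `*_mask.nrrd`, `labels.csv`.
#' @return list of subjects (`id`, `volume`, `label`).
#' @export
read_cohort <- function(dir) {
  labs <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(labs)), function(i) {
    id <- labs$subject_id[i]
    img <- read_nrrd(file.path(dir, paste0(id, "_image.nrrd")))
    msk <- read_nrrd(file.path(dir, paste0(id, "_mask.nrrd")))
    list(id = id,
         volume = volume_with_mask(img$data, img$spacing, msk$data == 1),
         label = labs$label[i])
  })
}
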