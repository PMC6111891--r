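## Data fusion and organization: ASCII sidecar tables next to the imagery,
## deterministic folder splitting (browsable folder sizes), and pooling of
## folders into uncompressed tar archives with checksum manifests for
## transfer/backup verification.

#' Write a metadata sidecar table for a set of images
#'
#' One row per image keyed by file name, schema tags as header — the
#' "separate ASCII text file next to the imagery" fusion route, which
#' survives any image-format limitation and keeps metadata editable
#' without touching pixels.
#'
#' @param images Character vector of image file names.
#' @param records Data frame of metadata records, one row per image.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(images, records, path) {
  if (length(images) != nrow(records))
    stop("every image needs exactly one record (", length(images),
         " images, ", nrow(records), " records)", call. = FALSE)
  out <- cbind(data.frame(name = images, stringsAsFactors = FALSE), records)
  write_metadata_table(out, path)
}

#' Plan a deterministic folder organization for a set of images
#'
#' Large surveys must be split into folders small enough to browse
#' (well under a thousand files). Two split rules: `"half_hour"` assigns
#' images to wall-clock half-hour windows (boundaries at hh:00:00.000 and
#' hh:30:00.000 UTC, half-open, so a full window of a 1 Hz stream holds
#' 1,800 images) and `"max_count"` packs at most `max_count` images per
#' folder in time order. Folder names combine the dive label with the
#' window start / running part number — meaningful for discovery, but not
#' a unique metadata store.
#'
#' @param images Character vector of image names.
#' @param t_ms Acquisition times (epoch ms), same length.
#' @param split `"half_hour"` or `"max_count"`.
#' @param dive Dive label used as folder-name prefix.
#' @param max_count Capacity for the `"max_count"` rule (default 999).
#' @param log Optional [curation_log()].
#' @return A `folder_plan`: data frame `name` / `t_ms` / `folder`.
#' @examples
#' organize_folders(c("a", "b"), subtime_to_ms(
#'   c("20150407 17:29:59.000", "20150407 17:30:00.000")))
#' @export
organize_folders <- function(images, t_ms, split = c("half_hour", "max_count"),
                             dive = "dive", max_count = 999L, log = NULL) {
  split <- match.arg(split)
  stopifnot(length(images) == length(t_ms), all(is.finite(t_ms)))
  ord <- order(t_ms)
  images <- images[ord]; t_ms <- t_ms[ord]
  if (split == "half_hour") {
    win <- floor(t_ms / 1800000)  # half-open half-hour windows
    start <- win * 1800000
    lab <- format(as.POSIXct(start / 1000, origin = "1970-01-01", tz = "UTC"),
                  "%Y%m%d_%H%M")
    folder <- paste0(dive, "_", lab)
  } else {
    stopifnot(max_count >= 1L)
    part <- (seq_along(images) - 1L) %/% max_count
    folder <- sprintf("%s_part%03d", dive, part + 1L)
  }
  plan <- data.frame(name = images, t_ms = t_ms, folder = folder,
                     stringsAsFactors = FALSE)
  class(plan) <- c("folder_plan", "data.frame")
  if (!is.null(log))
    log_append(log, "organize_folders",
               list(split = split, dive = dive,
                    max_count = if (split == "max_count") max_count else NULL),
               n_in = length(images), n_out = length(unique(folder)))
  plan
}

#' @export
print.folder_plan <- function(x, ...) {
  tab <- table(x$folder)
  cat("<folder_plan> ", nrow(x), " images in ", length(tab), " folders\n",
      sep = "")
  for (nm in names(tab)) cat(sprintf("  %-40s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Apply a folder plan on disk
#'
#' @param plan A [organize_folders()] plan.
#' @param from Directory holding the flat image files.
#' @param to Root directory for the organized tree.
#' @param action `"copy"` or `"move"`.
#' @return Invisibly, the vector of created folder paths.
#' @export
apply_folder_plan <- function(plan, from, to, action = c("copy", "move")) {
  action <- match.arg(action)
  for (f in unique(plan$folder))
    dir.create(file.path(to, f), recursive = TRUE, showWarnings = FALSE)
  src <- file.path(from, plan$name)
  dst <- file.path(to, plan$folder, plan$name)
  ok <- if (action == "copy") file.copy(src, dst, overwrite = TRUE)
  else file.rename(src, dst)
  if (!all(ok)) stop("failed to place ", sum(!ok), " files", call. = FALSE)
  invisible(file.path(to, unique(plan$folder)))
}

#' Pool folders into fixed-size uncompressed archives
#'
#' Greedy first-fit pooling of whole folders into uncompressed tar
#' archives of at most `target_size_bytes` (default 50 GB — large enough
#' to amortize per-file transfer overheads, small enough to move and
#' verify in units). A folder larger than the target gets a dedicated
#' oversize archive, with a warning. The manifest lists every member file
#' with its MD5 content checksum for duplicate/backup verification.
#'
#' @param folders Named numeric vector: folder sizes in bytes, or a data
#'   frame `folder`/`size_bytes`.
#' @param target_size_bytes Archive capacity (default 5e10).
#' @return An `archive_plan`: data frame `folder` / `size_bytes` /
#'   `archive`.
#' @export
pool_archives <- function(folders, target_size_bytes = 50e9) {
  if (is.data.frame(folders)) {
    sizes <- folders$size_bytes
    names(sizes) <- folders$folder
  } else sizes <- folders
  stopifnot(length(sizes) > 0, all(sizes >= 0), target_size_bytes > 0)
  archive <- integer(length(sizes))
  fill <- numeric(0)  # current fill of each open archive
  for (i in seq_along(sizes)) {
    if (sizes[i] > target_size_bytes) {
      warning("folder '", names(sizes)[i], "' (", sizes[i],
              " bytes) exceeds the archive target; dedicated oversize archive")
      fill <- c(fill, Inf)  # oversize archive accepts nothing else
      archive[i] <- length(fill)
      next
    }
    slot <- which(fill + sizes[i] <= target_size_bytes)[1]  # first fit
    if (is.na(slot)) {
      fill <- c(fill, sizes[i])
      slot <- length(fill)
    } else fill[slot] <- fill[slot] + sizes[i]
    archive[i] <- slot
  }
  plan <- data.frame(folder = names(sizes), size_bytes = as.numeric(sizes),
                     archive = sprintf("archive%03d", archive),
                     stringsAsFactors = FALSE)
  class(plan) <- c("archive_plan", "data.frame")
  plan
}

#' Create the archives of an archive plan and their checksum manifest
#'
#' @param plan An [pool_archives()] plan.
#' @param root Directory containing the folders.
#' @param out Output directory for `.tar` files and `manifest.tsv`.
#' @param log Optional [curation_log()].
#' @return Data frame manifest: `archive`, `member`, `size_bytes`, `md5`.
#' @export
create_archives <- function(plan, root, out, log = NULL) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  owd <- getwd()
  on.exit(setwd(owd))
  setwd(root)
  for (a in unique(plan$archive)) {
    members <- plan$folder[plan$archive == a]
    tarfile <- file.path(normalizePath(out), paste0(a, ".tar"))
    utils::tar(tarfile, files = members, compression = "none",
               tar = "internal")
    files <- unlist(lapply(members, function(m)
      list.files(m, recursive = TRUE, full.names = TRUE)))
    manifest[[a]] <- data.frame(
      archive = paste0(a, ".tar"), member = files,
      size_bytes = file.size(files),
      md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(log))
    log_append(log, "create_archives",
               list(archives = length(unique(plan$archive))),
               n_in = nrow(plan), n_out = nrow(manifest))
  manifest
}

#' Verify files against a checksum manifest
#'
#' @param manifest Manifest data frame (or path to `manifest.tsv`).
#' @param root Directory the member paths are relative to.
#' @return Data frame of mismatching/missing members (zero rows = intact).
#' @export
verify_manifest <- function(manifest, root = ".") {
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  path <- file.path(root, manifest$member)
  ok <- file.exists(path)
  md5 <- rep(NA_character_, length(path))
  md5[ok] <- unname(tools::md5sum(path[ok]))
  bad <- !ok | md5 != manifest$md5
  out <- manifest[bad, , drop = FALSE]
  out$observed_md5 <- md5[bad]
  rownames(out) <- NULL
  out
}
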