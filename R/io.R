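# Readers for annotated dish images and writers/readers for generated
# datasets. Images are PNG; annotations are JSON. Instance masks are stored
# as COCO-style uncompressed run-length encoding (column-major counts,
# starting with the number of leading zeros).

default_field_map <- function() {
  list(colonies = "colonies", x = "x", y = "y",
       width = "width", height = "height", species = "species")
}

read_png_rgb <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  a <- png::readPNG(path)
  if (is.matrix(a)) a <- array(rep(a, 3), dim = c(dim(a), 3L))
  if (dim(a)[3] == 2L) a <- array(rep(a[, , 1], 3), dim = c(dim(a)[1:2], 3L))
  if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

write_png_rgb <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, target = path)
}

new_annotated_dish <- function(image, annotations, source_id) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  structure(list(image = image, annotations = annotations,
                 source_id = source_id),
            class = "annotated_dish")
}

empty_annotations <- function() {
  data.frame(instance_id = integer(), x = numeric(), y = numeric(),
             w = numeric(), h = numeric(), species = character())
}

#' @export
print.annotated_dish <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<annotated_dish '%s'> %d x %d px, %d colonies (%s)\n",
              x$source_id, d[2], d[1], nrow(x$annotations),
              if (nrow(x$annotations)) paste(unique(x$annotations$species),
                                             collapse = ", ") else "empty"))
  invisible(x)
}

#' Read an annotated Petri-dish image
#'
#' Loads an RGB PNG plus its per-image annotation file: a JSON document with
#' a list of colony records, each carrying a bounding box `(x, y, width,
#' height)` and a species label. Boxes are clipped to the image frame on
#' load (clipping is reported via `message()`); boxes with no area left
#' after clipping are dropped with a warning.
#'
#' @param image_path path to an 8-bit PNG.
#' @param annotation_path path to the JSON annotation file.
#' @param species_labels permitted label set; an annotation outside it is an
#'   error.
#' @param field_map named list remapping the annotation dialect's field
#'   names (keys `colonies`, `x`, `y`, `width`, `height`, `species`) onto
#'   the file's actual keys; defaults to those names themselves.
#' @return an `annotated_dish`: list with `image` (`H x W x 3`, 0..255),
#'   `annotations` (data.frame `instance_id, x, y, w, h, species`) and
#'   `source_id`.
#' @export
read_annotated_dish <- function(image_path, annotation_path,
                                species_labels = agar_species(),
                                field_map = default_field_map()) {
  img <- read_png_rgb(image_path)
  if (!file.exists(annotation_path)) {
    stop("cannot read annotation file: ", annotation_path, call. = FALSE)
  }
  fm <- utils::modifyList(default_field_map(), field_map %||% list())
  ann <- jsonlite::fromJSON(annotation_path, simplifyDataFrame = FALSE)
  recs <- ann[[fm$colonies]] %||% list()
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- empty_annotations()
  kept <- 0L
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    sp <- as.character(r[[fm$species]])
    if (!sp %in% species_labels) {
      stop(sprintf("unknown species label '%s'; permitted labels: %s",
                   sp, paste(species_labels, collapse = ", ")), call. = FALSE)
    }
    b0 <- bbox(r[[fm$x]], r[[fm$y]], r[[fm$width]], r[[fm$height]])
    b <- bbox_clip(b0, W, H)
    if (b$w <= 0 || b$h <= 0) {
      warning(sprintf("dropping colony %d of %s: no area inside image after clipping",
                      i, basename(annotation_path)), call. = FALSE)
      next
    }
    if (b$x != b0$x || b$y != b0$y || b$w != b0$w || b$h != b0$h) {
      message(sprintf("clipped colony %d of %s to image bounds",
                      i, basename(annotation_path)))
    }
    kept <- kept + 1L
    out <- rbind(out, data.frame(instance_id = kept, x = b$x, y = b$y,
                                 w = b$w, h = b$h, species = sp))
  }
  new_annotated_dish(img, out, source_id = sub("\\.png$", "", basename(image_path)))
}

#' Write an annotated dish (image + annotation JSON)
#'
#' Inverse of [read_annotated_dish()]; used by the fixture generator and the
#' `fixtures` CLI subcommand.
#'
#' @param dish an `annotated_dish`.
#' @param image_path,annotation_path output paths.
#' @return `annotation_path`, invisibly.
#' @export
write_annotated_dish <- function(dish, image_path, annotation_path) {
  write_png_rgb(dish$image, image_path)
  cols <- lapply(seq_len(nrow(dish$annotations)), function(i) {
    a <- dish$annotations[i, ]
    list(x = a$x, y = a$y, width = a$w, height = a$h, species = a$species)
  })
  jsonlite::write_json(list(source_id = dish$source_id, colonies = cols),
                       annotation_path, auto_unbox = TRUE, digits = NA)
  invisible(annotation_path)
}

#' Run-length encode a binary mask (COCO convention)
#'
#' Column-major scan; the first count is the number of leading zeros (0 if
#' the mask starts with a foreground pixel).
#'
#' @param mask 0/1 matrix.
#' @return integer vector of counts.
#' @export
rle_encode <- function(mask) {
  v <- as.integer(as.vector(mask) > 0)
  r <- rle(v)
  counts <- r$lengths
  if (length(r$values) && r$values[1] == 1L) counts <- c(0L, counts)
  as.integer(counts)
}

#' Decode a run-length encoded mask
#'
#' @param counts integer counts as produced by [rle_encode()].
#' @param h,w mask dimensions.
#' @return 0/1 matrix `h x w`.
#' @export
rle_decode <- function(counts, h, w) {
  vals <- rep(rep_len(c(0L, 1L), length(counts)), counts)
  stopifnot(length(vals) == h * w)
  matrix(vals, nrow = h, ncol = w)
}

new_synth_patch_record <- function(image, annotations, masks, provenance) {
  stopifnot(nrow(annotations) == length(masks))
  structure(list(image = image, annotations = annotations, masks = masks,
                 provenance = provenance),
            class = "synth_patch_record")
}

#' Write a generated dataset to disk
#'
#' Writes patch images as PNG plus instance annotations, either as one
#' COCO-style JSON (`coco_json`: images / annotations with `bbox` and RLE
#' `segmentation` / categories) or as one JSON per image
#' (`per_image_json`). A `manifest.json` lists every image with its
#' annotation count and provenance; reading the dataset back reproduces
#' boxes, labels and masks exactly.
#'
#' @param records list of patch records from [generate_patch()] /
#'   [stylize_batch()].
#' @param out_dir output directory (created if missing).
#' @param format `"coco_json"` or `"per_image_json"`.
#' @param overwrite overwrite an existing manifest? Refuses by default.
#' @param extra named list merged into the manifest (e.g. run metadata).
#' @return path to `manifest.json`, invisibly.
#' @export
write_dataset <- function(records, out_dir,
                          format = c("coco_json", "per_image_json"),
                          overwrite = FALSE, extra = list()) {
  format <- match.arg(format)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists (use overwrite = TRUE): ", manifest_path,
         call. = FALSE)
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  species <- agar_species()
  img_entries <- vector("list", length(records))
  coco_images <- list(); coco_anns <- list(); ann_id <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    fname <- sprintf("patch_%05d.png", i)
    write_png_rgb(rec$image, file.path(out_dir, "images", fname))
    d <- dim(rec$image)
    img_entries[[i]] <- list(id = i, file = file.path("images", fname),
                             height = d[1], width = d[2],
                             n_annotations = nrow(rec$annotations),
                             provenance = rec$provenance)
    per_img_anns <- lapply(seq_len(nrow(rec$annotations)), function(k) {
      a <- rec$annotations[k, ]
      m <- rec$masks[[k]]
      list(bbox = c(a$x, a$y, a$w, a$h),
           category_id = match(a$species, species),
           species = a$species,
           segmentation = list(size = c(d[1], d[2]),
                               counts = rle_encode(m)))
    })
    if (format == "coco_json") {
      coco_images[[i]] <- list(id = i, file_name = file.path("images", fname),
                               height = d[1], width = d[2])
      for (k in seq_along(per_img_anns)) {
        ann_id <- ann_id + 1L
        e <- per_img_anns[[k]]
        coco_anns[[ann_id]] <- c(list(id = ann_id, image_id = i,
                                      iscrowd = 0,
                                      area = e$bbox[3] * e$bbox[4]),
                                 e[c("bbox", "category_id", "segmentation")])
      }
    } else {
      jsonlite::write_json(list(image = file.path("images", fname),
                                annotations = per_img_anns),
                           file.path(out_dir, sub("\\.png$", ".json", fname)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (format == "coco_json") {
    coco <- list(
      images = coco_images,
      annotations = coco_anns,
      categories = lapply(seq_along(species), function(j) {
        list(id = j, name = species[j])
      }))
    jsonlite::write_json(coco, file.path(out_dir, "annotations.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- c(list(format = format, n_images = length(records),
                     images = img_entries), extra)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param out_dir dataset directory containing `manifest.json`.
#' @return list of patch records (`image`, `annotations`, `masks`,
#'   `provenance`).
#' @export
read_dataset <- function(out_dir) {
  manifest <- jsonlite::fromJSON(file.path(out_dir, "manifest.json"),
                                 simplifyDataFrame = FALSE)
  species <- agar_species()
  per_image <- manifest$format == "per_image_json"
  coco <- NULL
  if (!per_image) {
    coco <- jsonlite::fromJSON(file.path(out_dir, "annotations.json"),
                               simplifyDataFrame = FALSE)
  }
  lapply(seq_along(manifest$images), function(i) {
    entry <- manifest$images[[i]]
    img <- read_png_rgb(file.path(out_dir, entry$file))
    if (per_image) {
      pj <- jsonlite::fromJSON(
        file.path(out_dir, sub("\\.png$", ".json", basename(entry$file))),
        simplifyDataFrame = FALSE)
      anns <- pj$annotations
    } else {
      anns <- Filter(function(a) a$image_id == entry$id, coco$annotations)
    }
    ann_df <- empty_annotations()
    masks <- list()
    for (k in seq_along(anns)) {
      a <- anns[[k]]
      bb <- unlist(a$bbox)
      ann_df <- rbind(ann_df, data.frame(
        instance_id = k, x = bb[1], y = bb[2], w = bb[3], h = bb[4],
        species = a$species %||% species[a$category_id]))
      sz <- unlist(a$segmentation$size)
      masks[[k]] <- rle_decode(unlist(a$segmentation$counts), sz[1], sz[2])
    }
    rownames(ann_df) <- NULL
    new_synth_patch_record(img, ann_df, masks, entry$provenance)
  })
}
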