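#' Specification for a synthetic image/report corpus
#'
#' The generator emulates the layout of a chest-radiograph reporting
#' dataset: grayscale PNG images paired with a short free-text findings
#' sentence through a JSON-lines manifest. Each image is a dark background
#' with a brighter thorax ellipse; each finding in the inventory, when
#' sampled, adds a bright Gaussian blob at a finding-specific region (with
#' a small seeded jitter), and contributes its template sentence to the
#' report. Findings are sampled independently per image; an image with no
#' finding receives the normal template. The image-to-report mapping is
#' therefore deterministic given the blob pattern, which is what makes the
#' corpus learnable end to end.
#'
#' @param n_images Number of images. Default 200.
#' @param size Image side length in pixels (square). Default 64.
#' @param inventory List of findings; each a list with `name`, `cx`, `cy`
#'   (blob centre as fractions of the image), `r` (blob radius, px) and
#'   `sentence` (lowercase alphabetic template). Default: three findings —
#'   focal opacity (left lung), enlarged cardiac silhouette, right pleural
#'   effusion.
#' @param normal_sentence Report used when no finding is sampled.
#' @param p_finding Per-finding independent inclusion probability.
#'   Default 0.35.
#' @param noise_sd Gaussian pixel noise standard deviation. Default 0.05
#'   (blob contrast ~0.6, so SNR is well above 5).
#' @param seed Integer RNG seed. Default 1.
#' @return List of class `cxr_synth_spec`.
#' @export
synth_spec <- function(n_images = 200L, size = 64L,
                       inventory = NULL,
                       normal_sentence = "the lungs are clear",
                       p_finding = 0.35, noise_sd = 0.05, seed = 1L) {
  if (is.null(inventory)) {
    inventory <- list(
      list(name = "opacity", cx = 0.30, cy = 0.35, r = 6,
           sentence = "there is an opacity in the left lung"),
      list(name = "cardiomegaly", cx = 0.55, cy = 0.70, r = 10,
           sentence = "the heart is enlarged"),
      list(name = "effusion", cx = 0.78, cy = 0.80, r = 7,
           sentence = "there is a pleural effusion on the right"))
  }
  if (length(inventory) == 0L) stop("finding inventory must be non-empty")
  words <- unlist(strsplit(c(normal_sentence,
                             vapply(inventory, `[[`, "", "sentence")), " "))
  if (any(words %in% c("startseq", "endseq")))
    stop("inventory sentences overlap the reserved tokens startseq/endseq")
  if (any(grepl("[^a-z]", words)))
    stop("inventory sentences must use lowercase alphabetic words only")
  structure(list(n_images = as.integer(n_images), size = as.integer(size),
                 inventory = inventory, normal_sentence = normal_sentence,
                 p_finding = p_finding, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cxr_synth_spec")
}

# One synthetic image given a logical vector of present findings.
synth_image <- function(spec, present, jitter) {
  s <- spec$size
  xs <- matrix(seq_len(s), s, s, byrow = TRUE)  # column index
  ys <- matrix(seq_len(s), s, s)                # row index
  img <- matrix(0.05, s, s)
  # thorax: centred ellipse, slightly brighter than background
  ell <- ((xs - s / 2) / (0.42 * s))^2 + ((ys - s / 2) / (0.46 * s))^2 <= 1
  img[ell] <- 0.25
  for (k in seq_along(spec$inventory)) {
    if (!present[k]) next
    f <- spec$inventory[[k]]
    cx <- f$cx * s + jitter[k, 1]
    cy <- f$cy * s + jitter[k, 2]
    blob <- 0.65 * exp(-(((xs - cx)^2 + (ys - cy)^2) / (2 * f$r^2)))
    img <- img + blob
  }
  img <- img + matrix(stats::rnorm(s * s, sd = spec$noise_sd), s, s)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic image/report corpus on disk
#'
#' Writes `n_images` grayscale 8-bit PNGs and a JSON-lines manifest
#' (`manifest.jsonl`) mapping each image to its report. The report is the
#' concatenation of the template sentences of the image's findings in fixed
#' inventory order, joined as sentences, or the normal template when no
#' finding was sampled. Byte-identical output at a fixed seed.
#'
#' @param spec A `cxr_synth_spec` (default [synth_spec()] defaults).
#' @param out_dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
generate_synth_corpus <- function(spec = synth_spec(), out_dir) {
  stopifnot(inherits(spec, "cxr_synth_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n_find <- length(spec$inventory)
  images <- character(spec$n_images)
  findings <- character(spec$n_images)
  for (i in seq_len(spec$n_images)) {
    present <- stats::runif(n_find) < spec$p_finding
    jitter <- matrix(stats::runif(2L * n_find, -2, 2), n_find, 2L)
    img <- synth_image(spec, present, jitter)
    fname <- sprintf("img_%04d.png", i)
    png::writePNG(img, file.path(out_dir, fname))
    sentences <- vapply(spec$inventory[present], `[[`, "", "sentence")
    if (length(sentences) == 0L) sentences <- spec$normal_sentence
    images[i] <- fname
    findings[i] <- paste0(paste(sentences, collapse = ". "), ".")
  }
  manifest <- file.path(out_dir, "manifest.jsonl")
  write_manifest(data.frame(image = images, findings = findings,
                            stringsAsFactors = FALSE), manifest)
  invisible(manifest)
}
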