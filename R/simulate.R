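## Synthetic chromatogram simulator.
##
## Generates templates, per-read quality profiles, four-channel traces
## built from Gaussian peaks, substitution / indel / secondary-peak
## injection with recorded ground truth, and file trees of valid ABIF
## files laid out the way real plate exports are (subdirectories, contig
## name + direction suffix). Everything is reproducible from a seed.

#' Simulation specification
#'
#' Defaults describe a typical two-plate barcode-style experiment: eight
#' contigs sequenced with one forward and one reverse read each, 600 bp
#' templates derived from a common ancestor, a Q50 quality plateau with
#' 20-base ramps down to Q5 at both read ends, clean traces (no
#' substitution errors, no secondary peaks) unless configured otherwise.
#'
#' @param n_contigs number of contig groups
#' @param directions read directions per contig (default one `F`, one `R`)
#' @param template_length template length in bases
#' @param gc_content template GC fraction
#' @param divergence_subs substitutions separating each contig's template
#'   from the shared ancestor
#' @param error_rate per-base substitution error rate in reads
#' @param peak_q,ramp_len,floor_q quality profile: plateau Phred score,
#'   ramp length at each end, end Phred score
#' @param secondary_count,secondary_ratio,secondary_positions secondary
#'   peak injection (count per read or explicit 1-based positions;
#'   intensity ratio)
#' @param indels list of indel injections, each
#'   `list(pos =, kind = "ins"/"del", bases =)`
#' @param peak_spacing,peak_sigma,peak_height,noise_sd trace geometry
#' @param subdirs subdirectory names for [write_fixture_tree()]
#' @param name_pattern file naming pattern with `{contig}` and `{dir}`
#'   fields (`dir` rendered as `F`/`R`)
#' @param seed integer seed driving all randomness
#' @return a `sim_spec` list
#' @export
simulation_spec <- function(n_contigs = 8, directions = c("forward", "reverse"),
                            template_length = 600, gc_content = 0.5,
                            divergence_subs = 10, error_rate = 0,
                            peak_q = 50, ramp_len = 20, floor_q = 5,
                            secondary_count = 0, secondary_ratio = 0.5,
                            secondary_positions = NULL, indels = list(),
                            peak_spacing = 12, peak_sigma = 3,
                            peak_height = 800, noise_sd = 2,
                            subdirs = c("plateA", "plateB"),
                            name_pattern = "{contig}_{dir}.ab1", seed = 1) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            secondary_ratio > 0, secondary_ratio <= 1)
  structure(as.list(environment()), class = "sim_spec")
}

#' Simulate a DNA template
#'
#' @param length template length (>= 1)
#' @param gc_content GC fraction
#' @param seed RNG seed (NULL: use current RNG state)
#' @param aa_reference if given, the template is an exact open reading
#'   frame of this amino-acid sequence (deterministic codon choice:
#'   lexicographically first codon per residue), and `length`/`gc_content`
#'   are ignored
#' @return DNA string
#' @export
simulate_template <- function(length = 600, gc_content = 0.5, seed = NULL,
                              aa_reference = NULL) {
  if (!is.null(aa_reference)) {
    aa <- seq_chars(load_aa_reference(aa_reference))
    gc <- Biostrings::GENETIC_CODE
    pick <- vapply(aa, function(a) {
      codons <- sort(names(gc)[gc == a])
      if (length(codons) == 0) stop_sk_value("no codon for residue '", a, "'")
      codons[1]
    }, "")
    return(paste(pick, collapse = ""))
  }
  stopifnot(length >= 1)
  with_seed(seed, {
    chars_seq(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                     prob = c((1 - gc_content) / 2, gc_content / 2,
                              gc_content / 2, (1 - gc_content) / 2)))
  })
}

quality_profile <- function(n, peak_q, ramp_len, floor_q) {
  q <- rep(peak_q, n)
  r <- min(ramp_len, n)
  if (r > 0) {
    ramp <- round(seq(floor_q, peak_q, length.out = r))
    q[seq_len(r)] <- pmin(q[seq_len(r)], ramp)
    q[n - seq_len(r) + 1L] <- pmin(q[n - seq_len(r) + 1L], ramp)
  }
  as.integer(q)
}

apply_substitutions <- function(chars, rate) {
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  errs <- list()
  for (p in hit) {
    from <- chars[p]
    to <- sample(setdiff(c("A", "C", "G", "T"), from), 1)
    chars[p] <- to
    errs[[length(errs) + 1L]] <- tibble::tibble(position = p, from = from, to = to)
  }
  list(chars = chars,
       errors = if (length(errs)) dplyr::bind_rows(errs) else
         tibble::tibble(position = integer(0), from = character(0),
                        to = character(0)))
}

apply_indels <- function(chars, indels) {
  # apply in decreasing position order so positions stay valid
  if (length(indels) == 0) return(chars)
  ord <- order(vapply(indels, `[[`, 1, "pos"), decreasing = TRUE)
  for (ind in indels[ord]) {
    pos <- ind$pos
    if (identical(ind$kind, "del")) {
      len <- ind$len %||% 1L
      chars <- chars[-(pos:(pos + len - 1L))]
    } else {
      chars <- append(chars, seq_chars(ind$bases %||% "A"), after = pos)
    }
  }
  chars
}

#' Simulate one Sanger read with its chromatogram
#'
#' The read observes the template (reverse reads observe its reverse
#' complement), with substitution errors at the configured rate and any
#' configured indels. The trace places a Gaussian peak of the called
#' base's channel at every basecall (spacing `peak_spacing` samples,
#' s.d. `peak_sigma`), plus low-level noise; injected secondary peaks add
#' the configured fraction of the primary amplitude on a recorded second
#' channel. Every injected feature is returned as ground truth for
#' oracle-style tests.
#'
#' @param template DNA template string
#' @param direction `"forward"` or `"reverse"`
#' @param spec a [simulation_spec()]
#' @param seed RNG seed for this read
#' @return list with `trace` ([trace_set()]), `seq` (called bases
#'   including injected errors), `qualities`, and `truth` (list with
#'   `errors` and `secondary` tibbles)
#' @export
simulate_read <- function(template, direction = "forward",
                          spec = simulation_spec(), seed = NULL) {
  with_seed(seed, {
    obs <- if (direction == "reverse") reverse_complement(template) else template
    chars <- seq_chars(obs)
    chars <- apply_indels(chars, spec$indels)
    sub <- apply_substitutions(chars, spec$error_rate)
    chars <- sub$chars
    n <- length(chars)
    qual <- quality_profile(n, spec$peak_q, spec$ramp_len, spec$floor_q)

    centers <- spec$peak_spacing %/% 2 + spec$peak_spacing * (seq_len(n) - 1L)
    L <- if (n) spec$peak_spacing * n + spec$peak_spacing else spec$peak_spacing
    channels <- list(A = numeric(L), C = numeric(L), G = numeric(L), T = numeric(L))
    heights <- stats::runif(n, 0.85, 1.15) * spec$peak_height
    support <- ceiling(4 * spec$peak_sigma)
    for (i in seq_len(n)) {
      ctr <- centers[i]
      win <- max(0, ctr - support):min(L - 1L, ctr + support)
      bump <- heights[i] * exp(-((win - ctr)^2) / (2 * spec$peak_sigma^2))
      ch <- chars[i]
      channels[[ch]][win + 1L] <- channels[[ch]][win + 1L] + bump
    }
    # secondary peaks
    sec_pos <- spec$secondary_positions
    if (is.null(sec_pos) && spec$secondary_count > 0) {
      lo <- spec$ramp_len + 5L; hi <- n - spec$ramp_len - 5L
      sec_pos <- sort(sample(lo:hi, min(spec$secondary_count, max(hi - lo + 1, 0))))
    }
    sec_rows <- list()
    for (p in sec_pos %||% integer(0)) {
      primary <- chars[p]
      secondary <- sample(setdiff(c("A", "C", "G", "T"), primary), 1)
      ctr <- centers[p]
      win <- max(0, ctr - support):min(L - 1L, ctr + support)
      bump <- spec$secondary_ratio * heights[p] *
        exp(-((win - ctr)^2) / (2 * spec$peak_sigma^2))
      channels[[secondary]][win + 1L] <- channels[[secondary]][win + 1L] + bump
      sec_rows[[length(sec_rows) + 1L]] <- tibble::tibble(
        position = p, primary_base = primary, secondary_base = secondary,
        ratio = spec$secondary_ratio)
    }
    if (spec$noise_sd > 0) {
      for (b in names(channels)) {
        channels[[b]] <- channels[[b]] +
          abs(stats::rnorm(L, 0, spec$noise_sd))
      }
    }
    channels <- lapply(channels, function(v) round(pmin(v, 32767)))
    trace <- trace_set(channels, peak_locations = centers, channel_order = "GATC")
    list(
      trace = trace, seq = chars_seq(chars), qualities = qual,
      truth = list(
        errors = sub$errors,
        secondary = if (length(sec_rows)) dplyr::bind_rows(sec_rows) else
          tibble::tibble(position = integer(0), primary_base = character(0),
                         secondary_base = character(0), ratio = numeric(0))
      )
    )
  })
}

render_name <- function(pattern, contig, direction) {
  out <- gsub("{contig}", contig, pattern, fixed = TRUE)
  gsub("{dir}", if (direction == "forward") "F" else "R", out, fixed = TRUE)
}

#' Write a simulated ABIF fixture tree
#'
#' Creates per-contig templates (a shared ancestor plus per-contig
#' substitutions), simulates each read, and writes valid ABIF files into
#' the configured subdirectories with the contig-plus-direction naming
#' convention. A grouping CSV and a JSON manifest (files, directions,
#' contigs, templates and injected truth) are written alongside.
#'
#' @param spec a [simulation_spec()]
#' @param root_dir output directory
#' @param force overwrite a non-empty `root_dir`?
#' @return the manifest, invisibly: a list with `files` (tibble) and
#'   `templates` (named character)
#' @export
write_fixture_tree <- function(spec = simulation_spec(), root_dir,
                               force = FALSE) {
  if (dir.exists(root_dir) && length(list.files(root_dir)) > 0 && !force)
    stop_sk_value("refusing to write into non-empty directory ", root_dir,
                  " (use force = TRUE)")
  dir.create(root_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in spec$subdirs) dir.create(file.path(root_dir, d), showWarnings = FALSE)

  ancestor <- simulate_template(spec$template_length, spec$gc_content,
                                seed = spec$seed)
  rows <- list()
  templates <- character(0)
  truth <- list()
  for (ci in seq_len(spec$n_contigs)) {
    contig <- sprintf("contig%02d", ci)
    tmpl <- with_seed(spec$seed + ci, {
      ch <- seq_chars(ancestor)
      if (spec$divergence_subs > 0) {
        pos <- sample(length(ch), min(spec$divergence_subs, length(ch)))
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      }
      chars_seq(ch)
    })
    templates[contig] <- tmpl
    subdir <- spec$subdirs[((ci - 1L) %% length(spec$subdirs)) + 1L]
    for (di in seq_along(spec$directions)) {
      dirn <- spec$directions[di]
      read_seed <- spec$seed + 1000L * ci + di
      sim <- simulate_read(tmpl, dirn, spec, seed = read_seed)
      fname <- render_name(spec$name_pattern, contig, dirn)
      path <- file.path(root_dir, subdir, fname)
      write_abif(sim$trace, sim$seq, sim$qualities, path)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        file = file.path(subdir, fname), contig = contig, direction = dirn,
        seed = read_seed, n_bases = nchar(sim$seq))
      truth[[file.path(subdir, fname)]] <- sim$truth
    }
  }
  files <- dplyr::bind_rows(rows)
  csv <- data.frame(reads = files$file,
                    direction = ifelse(files$direction == "forward", "F", "R"),
                    contig = files$contig)
  utils::write.csv(csv, file.path(root_dir, "grouping.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- list(files = files, templates = templates,
                   truth = truth, spec = unclass(spec))
  jsonlite::write_json(
    list(files = files, templates = as.list(templates),
         spec = unclass(spec)[setdiff(names(spec), "indels")]),
    file.path(root_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
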