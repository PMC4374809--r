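# Genotype-conditional synthetic small-RNA read generator.
#
# The generator emits the read populations the analysis is designed to
# detect: antisense 22G reads (5'-G enforced by sampling 5' ends only at
# template-C positions) in a target-site proximal window (secondary siRNAs)
# and over the remaining coding sequence (tertiary siRNAs), background
# antisense reads, and sense his-58 normalizer fragments. Which populations
# are present is controlled by the genotype's epistasis flags: tertiary
# production requires secondary production, and both require an intact
# piRNA/Mutator axis. Region read counts are Poisson; 5'-end positions are
# uniform over the template-C positions of the region. Every emitted read is
# an exact (reverse-complement) substring of the spliced reference, so exact
# alignment recovers it, and none spans an intron.

#' Genotype scenario flags
#'
#' @param name Genotype label.
#' @param secondary_active Does the genotype make secondary (target-site
#'   proximal) 22G-RNAs? `FALSE` for piRNA-pathway / 22G-biogenesis mutants
#'   (prg-1, mut-16, rrf-1;ego-1, drh-3).
#' @param tertiary_active Does it make tertiary (distal) 22G-RNAs? `FALSE`
#'   for nuclear RNAi mutants (hrde-1, nrde-1, nrde-4) and necessarily
#'   whenever `secondary_active` is `FALSE`.
#' @return A `genotype_spec` list.
#' @export
genotype_spec <- function(name, secondary_active = TRUE, tertiary_active = TRUE) {
  if (tertiary_active && !secondary_active) {
    stop2("tertiary_active requires secondary_active (epistasis: tertiary ",
          "siRNAs form downstream of secondary siRNAs)")
  }
  structure(list(name = name, secondary_active = secondary_active,
                 tertiary_active = tertiary_active),
            class = "genotype_spec")
}

#' Built-in genotype presets
#'
#' @param name One of `"wild_type"`, `"prg-1"`, `"mut-16"`, `"rrf-1;ego-1"`,
#'   `"drh-3"`, `"hrde-1"`, `"nrde-1"`, `"nrde-4"`.
#' @return A [genotype_spec()].
#' @export
genotype_preset <- function(name) {
  presets <- list(
    "wild_type"   = c(TRUE, TRUE),
    "prg-1"       = c(FALSE, FALSE),
    "mut-16"      = c(FALSE, FALSE),
    "rrf-1;ego-1" = c(FALSE, FALSE),
    "drh-3"       = c(FALSE, FALSE),
    "hrde-1"      = c(TRUE, FALSE),
    "nrde-1"      = c(TRUE, FALSE),
    "nrde-4"      = c(TRUE, FALSE)
  )
  if (!name %in% names(presets)) {
    stop2("unknown genotype preset: ", name, " (known: ",
          paste(names(presets), collapse = ", "), ")")
  }
  f <- presets[[name]]
  genotype_spec(name, f[1L], f[2L])
}

#' Simulation configuration
#'
#' Rates are expected antisense 22G reads per nucleotide per unit depth, so
#' the expected read count of a region is `lambda * region_nt * depth`.
#' Defaults are chosen for detectability at `depth = 1e5` and are the
#' generator's own parameters, not biological estimates.
#'
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param depth Sequencing-depth scaling factor (expected total read count
#'   order of magnitude).
#' @param lambda_proximal,lambda_distal,lambda_background Per-nt, per-unit-
#'   depth antisense 22G rates for the proximal window, the distal coding
#'   remainder and nonspecific background.
#' @param proximal_window Half-width (nt) of the proximal window around the
#'   target site.
#' @param read_length_probs Probabilities over read lengths 21/22/23 nt.
#' @param his58_rate Expected normalizer reads per unit depth.
#' @param ip_fold IP enrichment weight of construct-antisense reads (>= 1).
#' @param n_genes,fraction_cluster6_like,fraction_cluster1_like Genome-panel
#'   composition: genes with 3'-half piRNA sites that lose 5' reads in
#'   nuclear RNAi mutants (cluster6-like), the mirrored class
#'   (cluster1-like), and the remainder (hotspot/uniform genes).
#' @param panel_targeted_mean Expected reads per transcript half of a
#'   targeted panel gene (per unit depth relative to 1e5).
#' @param panel_hotspot_mean,panel_uniform_mean Expected reads of a hotspot
#'   gene's peak bin / of a uniform gene.
#' @param n_pirnas Size of the synthetic piRNA panel.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       depth = 1e5,
                       lambda_proximal = 2e-5,
                       lambda_distal = 2e-5,
                       lambda_background = 2e-7,
                       proximal_window = 200L,
                       read_length_probs = c(`21` = 0.15, `22` = 0.70, `23` = 0.15),
                       his58_rate = 0.02,
                       ip_fold = 10,
                       n_genes = 300L,
                       fraction_cluster6_like = 0.5,
                       fraction_cluster1_like = 0.2,
                       panel_targeted_mean = 120,
                       panel_hotspot_mean = 100,
                       panel_uniform_mean = 60,
                       n_pirnas = 50L) {
  rates <- c(lambda_proximal, lambda_distal, lambda_background, his58_rate,
             panel_targeted_mean, panel_hotspot_mean, panel_uniform_mean)
  if (any(rates < 0)) stop2("rates must be >= 0")
  if (abs(sum(read_length_probs) - 1) > 1e-9) stop2("read_length_probs must sum to 1")
  if (proximal_window < 0) stop2("proximal_window must be >= 0")
  if (fraction_cluster6_like + fraction_cluster1_like > 1) {
    stop2("class fractions sum to more than 1")
  }
  structure(list(seed = as.integer(seed), depth = depth,
                 lambda_proximal = lambda_proximal,
                 lambda_distal = lambda_distal,
                 lambda_background = lambda_background,
                 proximal_window = as.integer(proximal_window),
                 read_length_probs = read_length_probs,
                 his58_rate = his58_rate, ip_fold = ip_fold,
                 n_genes = as.integer(n_genes),
                 fraction_cluster6_like = fraction_cluster6_like,
                 fraction_cluster1_like = fraction_cluster1_like,
                 panel_targeted_mean = panel_targeted_mean,
                 panel_hotspot_mean = panel_hotspot_mean,
                 panel_uniform_mean = panel_uniform_mean,
                 n_pirnas = as.integer(n_pirnas)),
            class = "sim_config")
}

# ---- low-level read emitters (caller seeds the RNG) ------------------------

# Antisense reads with 5' ends drawn uniformly from `cand5` (0-based
# template-C positions); mean count is Poisson. Returns a provenance df.
.emit_antisense <- function(seq, revseq, cand5, mean_n, len_probs, class,
                            tid, window_name) {
  if (mean_n <= 0) return(NULL)
  if (length(cand5) == 0L) {
    stop2("no template-C position available in window '", window_name,
          "' of ", tid, " (degenerate sequence)")
  }
  n <- stats::rpois(1L, mean_n)
  if (n == 0L) return(NULL)
  L <- nchar(seq)
  e <- sample(cand5, n, replace = TRUE)
  len <- as.integer(sample(names(len_probs), n, replace = TRUE, prob = len_probs))
  s <- e - len + 1L
  keep <- s >= 0L
  e <- e[keep]; s <- s[keep]
  if (!length(e)) return(NULL)
  data.frame(sequence = substring(revseq, L - e, L - s),
             transcript_id = tid, start = s, end = e + 1L,
             orientation = "antisense", class = class,
             stringsAsFactors = FALSE)
}

# Sense fragments fully contained in [lo, hi) (0-based half-open).
.emit_sense <- function(seq, lo, hi, mean_n, len_probs, class, tid) {
  if (mean_n <= 0) return(NULL)
  n <- stats::rpois(1L, mean_n)
  if (n == 0L) return(NULL)
  len <- as.integer(sample(names(len_probs), n, replace = TRUE, prob = len_probs))
  smax <- hi - len
  keep <- smax >= lo
  len <- len[keep]; smax <- smax[keep]
  if (!length(len)) return(NULL)
  s <- lo + floor(stats::runif(length(len)) * (smax - lo + 1L))
  data.frame(sequence = substring(seq, s + 1L, s + len),
             transcript_id = tid, start = as.integer(s),
             end = as.integer(s + len),
             orientation = "sense", class = class,
             stringsAsFactors = FALSE)
}

.assemble_read_set <- function(parts, prefix, label) {
  parts <- parts[!vapply(parts, is.null, TRUE)]
  df <- if (length(parts)) do.call(rbind, parts) else
    data.frame(sequence = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0),
               orientation = character(0), class = character(0),
               stringsAsFactors = FALSE)
  df <- cbind(read_id = sprintf("%s_%06d", prefix, seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  read_set(df, label = label)
}

# ---- sensor / construct scenarios ------------------------------------------

#' Simulate a piRNA-sensor sequencing library for one genotype
#'
#' Proximal (secondary) antisense 22G reads are emitted uniformly over the
#' target site +/- `proximal_window` when the genotype makes secondary
#' siRNAs; distal (tertiary) reads over the remaining coding sequence when
#' it makes tertiary siRNAs; background antisense reads over the whole
#' construct; and sense his-58 normalizer fragments. See the package
#' vignette for why normalizer fragments are emitted sense-strand.
#'
#' @param cfg A [sim_config()].
#' @param genotype A [genotype_spec()] or preset name.
#' @param construct A [build_transgene()] construct with a target site.
#' @return List with `reads` (a [read_set()]) and `truth` (expected counts
#'   and regions).
#' @export
simulate_sensor_scenario <- function(cfg, genotype, construct = sensor_construct()) {
  if (is.character(genotype)) genotype <- genotype_preset(genotype)
  if (is.null(construct$target_site_interval)) {
    stop2("construct ", construct$id, " has no target_site segment")
  }
  site <- construct$target_site_interval
  L <- construct$spliced_length
  w <- cfg$proximal_window
  prox <- seq.int(max(0L, site[1L] - w), min(L, site[2L] + w) - 1L)
  seg <- construct$segments
  coding_rows <- seg$role %in% c("coding", "normalizer", "linker")
  coding <- unlist(lapply(which(coding_rows), function(i)
    seq.int(seg$start[i], seg$end[i] - 1L)))
  distal <- setdiff(coding, prox)
  all_pos <- seq.int(0L, L - 1L)
  regions <- list(
    proximal = list(pos = prox,
                    mean = if (genotype$secondary_active)
                      cfg$lambda_proximal * length(prox) * cfg$depth else 0),
    distal = list(pos = distal,
                  mean = if (genotype$tertiary_active)
                    cfg$lambda_distal * length(distal) * cfg$depth else 0),
    background = list(pos = all_pos,
                      mean = cfg$lambda_background * L * cfg$depth)
  )
  cpos <- base_positions(construct$sequence)
  revseq <- revcomp(construct$sequence)
  norm_row <- which(seg$role == "normalizer")
  with_seed(cfg$seed, {
    parts <- lapply(names(regions), function(nm) {
      r <- regions[[nm]]
      .emit_antisense(construct$sequence, revseq, intersect(cpos, r$pos),
                      r$mean, cfg$read_length_probs, nm, construct$id, nm)
    })
    if (length(norm_row)) {
      parts <- c(parts, list(.emit_sense(construct$sequence,
                                         seg$start[norm_row[1L]],
                                         seg$end[norm_row[1L]],
                                         cfg$his58_rate * cfg$depth,
                                         cfg$read_length_probs,
                                         "normalizer", construct$id)))
    }
    reads <- .assemble_read_set(parts, paste0(construct$id, "_", genotype$name),
                                genotype$name)
  })
  truth <- list(
    transcript_id = construct$id,
    genotype = genotype,
    site = site,
    proximal_region = range(prox),
    expected = vapply(regions, function(r) r$mean, numeric(1)),
    class_counts = table(factor(reads$class,
                                levels = c(names(regions), "normalizer")))
  )
  list(reads = reads, truth = truth, construct = construct)
}

#' Named scenario presets
#'
#' Shipped scenario presets: `sensor_wt`, `sensor_prg1`, `sensor_mut16`,
#' `sensor_hrde1`, `sensor_nrde` (the sensor construct under the matching
#' genotype); `operon_trans_silenced` (tertiary reads across GFP, linker and
#' mCherry), `operon_outcrossed` (GFP-antisense level reduced after
#' outcrossing the initiating sensor), `rnai_feeding_P0` (reads confined to
#' the GFP trigger) and `rnai_feeding_F2` (inherited response spread across
#' the operon); `sensor_ip` (a wild-type sensor library diluted in
#' nonspecific background reads, the substrate for [simulate_ip_pair()]).
#'
#' @param name Preset name.
#' @param cfg A [sim_config()].
#' @return List with `reads`, `truth`, and `construct`.
#' @export
simulate_scenario <- function(name, cfg = sim_config()) {
  sensor_map <- c(sensor_wt = "wild_type", sensor_prg1 = "prg-1",
                  sensor_mut16 = "mut-16", sensor_hrde1 = "hrde-1",
                  sensor_nrde = "nrde-4")
  if (name %in% names(sensor_map)) {
    cons <- sensor_construct()
    out <- simulate_sensor_scenario(cfg, sensor_map[[name]], cons)
    out$construct <- cons
    return(out)
  }
  if (name %in% c("operon_trans_silenced", "operon_outcrossed",
                  "rnai_feeding_P0", "rnai_feeding_F2")) {
    return(.simulate_operon_preset(name, cfg))
  }
  if (name == "sensor_ip") return(.simulate_ip_base(cfg))
  stop2("unknown scenario preset: ", name)
}

# Operon scenarios: GFP is the homology region through which silencing
# enters (the "proximal analog"); mCherry + linker carry tertiary reads.
.simulate_operon_preset <- function(name, cfg) {
  cons <- operon_construct()
  seg <- cons$segments
  pos_of <- function(nm) {
    i <- which(seg$name == nm)
    seq.int(seg$start[i], seg$end[i] - 1L)
  }
  gfp <- pos_of("GFP")
  mch <- c(pos_of("mCherry"), pos_of("gpd-2_linker"))
  gfp_mean <- cfg$lambda_proximal * length(gfp) * cfg$depth
  mch_mean <- cfg$lambda_distal * length(mch) * cfg$depth
  means <- switch(name,
    operon_trans_silenced = c(gfp = gfp_mean, mcherry = mch_mean),
    operon_outcrossed     = c(gfp = 0.3 * gfp_mean, mcherry = mch_mean),
    rnai_feeding_P0       = c(gfp = gfp_mean, mcherry = 0),
    rnai_feeding_F2       = c(gfp = gfp_mean, mcherry = mch_mean))
  cpos <- base_positions(cons$sequence)
  revseq <- revcomp(cons$sequence)
  L <- cons$spliced_length
  with_seed(cfg$seed, {
    parts <- list(
      .emit_antisense(cons$sequence, revseq, intersect(cpos, gfp),
                      means[["gfp"]], cfg$read_length_probs, "proximal",
                      cons$id, "GFP"),
      .emit_antisense(cons$sequence, revseq, intersect(cpos, mch),
                      means[["mcherry"]], cfg$read_length_probs, "distal",
                      cons$id, "mCherry+linker"),
      .emit_antisense(cons$sequence, revseq, cpos,
                      cfg$lambda_background * L * cfg$depth,
                      cfg$read_length_probs, "background", cons$id, "construct")
    )
    reads <- .assemble_read_set(parts, paste0(cons$id, "_", name), name)
  })
  list(reads = reads,
       truth = list(transcript_id = cons$id, expected = means,
                    gfp_region = range(gfp), mcherry_region = range(mch)),
       construct = cons)
}

# Wild-type sensor library diluted ~1:100 in nonspecific background reads
# (random sequences that match nothing); the IP base fixture.
.simulate_ip_base <- function(cfg) {
  sensor_cfg <- cfg
  sensor_cfg$lambda_proximal <- cfg$lambda_proximal / 3
  sensor_cfg$lambda_distal <- cfg$lambda_distal / 3
  sensor_cfg$his58_rate <- 0
  cons <- sensor_construct()
  base <- simulate_sensor_scenario(sensor_cfg, "wild_type", cons)
  n_bg <- max(0L, round(cfg$depth) - nrow(base$reads))
  with_seed(cfg$seed + 104729L, {
    lens <- as.integer(sample(names(cfg$read_length_probs), n_bg,
                              replace = TRUE, prob = cfg$read_length_probs))
    bg <- data.frame(read_id = sprintf("bgpool_%06d", seq_len(n_bg)),
                     sequence = random_dna(n_bg, lens),
                     transcript_id = NA_character_, start = NA_integer_,
                     end = NA_integer_, orientation = "none",
                     class = "background", stringsAsFactors = FALSE)
  })
  reads <- read_set(rbind(as.data.frame(base$reads), bg), label = "sensor_ip")
  list(reads = reads, truth = base$truth, construct = cons)
}

#' Simulate an input/IP library pair
#'
#' The IP library resamples the base library with weight `ip_fold` on
#' construct-antisense reads (any non-background antisense class) and
#' weight 1 on everything else; the control IP (from the deletion mutant,
#' where the antibody pulls nothing specific) resamples uniformly.
#'
#' @param cfg A [sim_config()] (uses `ip_fold`, `seed`).
#' @param base A provenance-tagged [read_set()].
#' @return List of [read_set()]s: `input`, `ip`, `ip_control`.
#' @export
simulate_ip_pair <- function(cfg, base) {
  if (nrow(base) == 0L) stop2("empty base read set")
  if (cfg$ip_fold < 1) stop2("ip_fold must be >= 1")
  w <- ifelse(base$orientation == "antisense" & base$class != "background",
              cfg$ip_fold, 1)
  n <- nrow(base)
  with_seed(cfg$seed + 7919L, {
    ip <- as.data.frame(base)[sample.int(n, n, replace = TRUE, prob = w), ]
    ctrl <- as.data.frame(base)[sample.int(n, n, replace = TRUE), ]
  })
  ip$read_id <- sprintf("ip_%06d", seq_len(n))
  ctrl$read_id <- sprintf("ipctrl_%06d", seq_len(n))
  rownames(ip) <- rownames(ctrl) <- NULL
  list(input = base,
       ip = read_set(ip, label = paste0(attr(base, "label"), "_IP")),
       ip_control = read_set(ctrl, label = paste0(attr(base, "label"), "_IPctrl")))
}

# ---- genome panel ----------------------------------------------------------

#' Simulate a genome-like panel of genes with read sets per genotype
#'
#' Generates `n_genes` spliced transcripts (1-3 exons, both strands) in four
#' pattern classes: `cluster6_like` genes carry piRNA target sites in their
#' 3' half, have antisense 22G reads over the whole gene in wild type, and
#' lose the 5'-half (tertiary) reads in the nuclear RNAi mutant;
#' `cluster1_like` genes mirror this; `hotspot` genes have a localized read
#' peak at a random bin (with a site at a random position) unchanged across
#' genotypes; `uniform` genes have untargeted uniform background reads. The
#' prg-1 library removes all targeted-gene 22Gs. Reads are emitted from the
#' spliced template only.
#'
#' @param cfg A [sim_config()].
#' @return List: `references` (transcript models), `pirnas`, `read_sets`
#'   (named list for `wild_type`, `nrde-4`, `prg-1`), `truth` (per-gene
#'   data.frame + per-gene site table), `config`.
#' @export
simulate_genome_panel <- function(cfg = sim_config()) {
  if (cfg$n_genes < 10L) stop2("n_genes must be >= 10")
  if (cfg$fraction_cluster6_like + cfg$fraction_cluster1_like > 1) {
    stop2("class fractions sum to more than 1")
  }
  n6 <- round(cfg$fraction_cluster6_like * cfg$n_genes)
  n1 <- round(cfg$fraction_cluster1_like * cfg$n_genes)
  n_other <- cfg$n_genes - n6 - n1
  n_hot <- round(2 / 3 * n_other)
  n_uni <- n_other - n_hot
  classes <- c(rep("cluster6_like", n6), rep("cluster1_like", n1),
               rep("hotspot", n_hot), rep("uniform", n_uni))
  pirnas <- builtin_pirnas(cfg$n_pirnas)
  scale <- cfg$depth / 1e5

  with_seed(cfg$seed, {
    genes <- vector("list", cfg$n_genes)
    site_rows <- list()
    for (g in seq_len(cfg$n_genes)) {
      id <- sprintf("gene%03d", g)
      L <- sample(900:1800, 1L)
      seq <- random_dna(1, L)
      cls <- classes[g]
      half <- L %/% 2L
      peak_bin <- NA_integer_
      # implant target sites (exact antisense matches of panel piRNAs)
      n_sites <- switch(cls, cluster6_like = sample(1:3, 1L),
                        cluster1_like = sample(1:3, 1L),
                        hotspot = 1L, uniform = 0L)
      starts <- integer(0)
      if (n_sites > 0L) {
        rng <- switch(cls,
          cluster6_like = c(half, L - 21L),        # midpoint start+10 >= half
          cluster1_like = c(0L, half - 11L),       # midpoint < half
          hotspot = c(0L, L - 21L))
        avail <- seq.int(rng[1L], rng[2L])
        for (k in seq_len(n_sites)) {
          if (!length(avail)) break
          s <- sample(avail, 1L)
          starts <- c(starts, s)
          avail <- avail[abs(avail - s) >= 21L]
        }
        pir_ids <- sample(names(pirnas), length(starts), replace = TRUE)
        for (k in seq_along(starts)) {
          site_seq <- revcomp(unname(pirnas[[pir_ids[k]]]))
          substr(seq, starts[k] + 1L, starts[k] + 21L) <- site_seq
        }
        site_rows[[length(site_rows) + 1L]] <-
          data.frame(transcript_id = id, pirna_id = pir_ids,
                     start = starts,
                     half = position_in_half(L, starts + 10L),
                     stringsAsFactors = FALSE)
      }
      if (cls == "hotspot") peak_bin <- sample(1:10, 1L)
      # exon structure: 1-3 exons with introns, random strand
      n_ex <- sample(1:3, 1L)
      cuts <- if (n_ex > 1L) sort(sample(seq.int(50L, L - 50L), n_ex - 1L)) else integer(0)
      bounds <- c(0L, cuts, L)
      widths <- diff(bounds)
      introns <- if (n_ex > 1L) sample(60:200, n_ex - 1L, replace = TRUE) else integer(0)
      gstart <- cumsum(c(0L, head(widths, -1L) + introns))
      exons <- cbind(start = gstart, end = gstart + widths)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        # genomic exon order must be by genomic start; spliced order handled
        # by map_to_genomic. Reverse block layout so exon1 is genomic-last.
        total_span <- exons[nrow(exons), "end"]
        exons <- cbind(start = total_span - rev(exons[, "end"]),
                       end = total_span - rev(exons[, "start"]))
      }
      genes[[g]] <- list(model = transcript_model(id, seq, exons = exons,
                                                  strand = strand),
                         class = cls, peak_bin = peak_bin,
                         revseq = revcomp(seq), cpos = base_positions(seq))
    }

    # read sets per genotype
    genotypes <- c("wild_type", "nrde-4", "prg-1")
    read_sets <- lapply(genotypes, function(gt) {
      parts <- vector("list", cfg$n_genes)
      for (g in seq_len(cfg$n_genes)) {
        gene <- genes[[g]]
        t <- gene$model
        L <- t$spliced_length
        half <- L %/% 2L
        cpos <- gene$cpos
        revseq <- gene$revseq
        pos5 <- seq.int(0L, half - 1L)
        pos3 <- seq.int(half, L - 1L)
        regions <- list()
        tm <- cfg$panel_targeted_mean * scale
        if (gene$class == "cluster6_like") {
          if (gt == "wild_type") {
            regions <- list(targeted_5 = list(pos = pos5, mean = tm),
                            targeted_3 = list(pos = pos3, mean = tm))
          } else if (gt == "nrde-4") {
            regions <- list(targeted_3 = list(pos = pos3, mean = tm))
          }
        } else if (gene$class == "cluster1_like") {
          if (gt == "wild_type") {
            regions <- list(targeted_5 = list(pos = pos5, mean = tm),
                            targeted_3 = list(pos = pos3, mean = tm))
          } else if (gt == "nrde-4") {
            regions <- list(targeted_5 = list(pos = pos5, mean = tm))
          }
        } else if (gene$class == "hotspot") {
          b <- gene$peak_bin
          peak <- seq.int(floor((b - 1L) * L / 10), floor(b * L / 10) - 1L)
          # targeted genes carry low-level 22G coverage along the gene body
          # in addition to the localized peak
          regions <- list(hotspot = list(pos = peak,
                                         mean = cfg$panel_hotspot_mean * scale),
                          hotspot_body = list(pos = seq.int(0L, L - 1L),
                                              mean = 0.3 * cfg$panel_hotspot_mean * scale))
        } else {
          regions <- list(uniform = list(pos = seq.int(0L, L - 1L),
                                         mean = cfg$panel_uniform_mean * scale))
        }
        regions$background <- list(pos = seq.int(0L, L - 1L),
                                   mean = cfg$lambda_background * L * cfg$depth)
        emitted <- lapply(names(regions), function(nm) {
          r <- regions[[nm]]
          .emit_antisense(t$sequence, revseq, intersect(cpos, r$pos), r$mean,
                          cfg$read_length_probs, nm, t$id, nm)
        })
        parts[[g]] <- do.call(rbind, emitted[!vapply(emitted, is.null, TRUE)])
      }
      .assemble_read_set(parts, gt, gt)
    })
    names(read_sets) <- genotypes
  })

  truth_genes <- data.frame(
    transcript_id = vapply(genes, function(g) g$model$id, ""),
    class = classes,
    spliced_length = vapply(genes, function(g) g$model$spliced_length, 0L),
    peak_bin = vapply(genes, function(g) g$peak_bin %||% NA_integer_, 0L),
    targeted = classes %in% c("cluster6_like", "cluster1_like", "hotspot"),
    stringsAsFactors = FALSE
  )
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(transcript_id = character(0), pirna_id = character(0),
               start = integer(0), half = character(0))
  refs <- lapply(genes, `[[`, "model")
  names(refs) <- truth_genes$transcript_id
  list(references = refs, pirnas = pirnas, read_sets = read_sets,
       truth = list(genes = truth_genes, sites = sites), config = cfg)
}

# ---- fixture writer --------------------------------------------------------

#' Write a simulation to disk as plain-text fixtures
#'
#' Writes reference FASTA (+BED12), piRNA FASTA, one FASTQ per read set,
#' truth TSVs, and a JSON manifest echoing the seed and config with
#' per-file record counts and checksums.
#'
#' @param dir Output directory (created if needed).
#' @param sim Output of [simulate_genome_panel()] or a scenario (list with
#'   `reads`, `truth`, `construct`).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_fixture <- function(dir, sim) {
  if (file.exists(dir) && !dir.exists(dir)) {
    stop2("output path is not a writable directory: ", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(dir, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop2("output path is not a writable directory: ", dir)
  unlink(probe)
  files <- list()
  add <- function(path, records) {
    files[[length(files) + 1L]] <<- list(
      file = basename(path), records = records,
      md5 = unname(tools::md5sum(path)))
  }
  refs <- if (!is.null(sim$references)) sim$references else list(sim$construct)
  fa <- file.path(dir, "references.fasta")
  bed <- file.path(dir, "references.bed")
  write_references(refs, fa, bed)
  add(fa, length(refs)); add(bed, length(refs))
  if (!is.null(sim$pirnas)) {
    pfa <- file.path(dir, "pirnas.fasta")
    ss <- Biostrings::DNAStringSet(sim$pirnas)
    Biostrings::writeXStringSet(ss, pfa)
    add(pfa, length(sim$pirnas))
  }
  sets <- if (!is.null(sim$read_sets)) sim$read_sets else
    stats::setNames(list(sim$reads), attr(sim$reads, "label") %||% "reads")
  for (nm in names(sets)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
    fq <- file.path(dir, paste0("reads_", safe, ".fastq"))
    write_fastq(sets[[nm]], fq)
    add(fq, nrow(sets[[nm]]))
    tt <- file.path(dir, paste0("truth_reads_", safe, ".tsv"))
    utils::write.table(as.data.frame(sets[[nm]]), tt, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add(tt, nrow(sets[[nm]]))
  }
  if (!is.null(sim$truth$genes)) {
    tg <- file.path(dir, "truth_genes.tsv")
    utils::write.table(sim$truth$genes, tg, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(tg, nrow(sim$truth$genes))
    ts <- file.path(dir, "truth_sites.tsv")
    utils::write.table(sim$truth$sites, ts, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(ts, nrow(sim$truth$sites))
  }
  cfg <- sim$config %||% NULL
  manifest <- list(seed = cfg$seed %||% NA, config = cfg, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
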