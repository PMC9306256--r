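# Synthetic-data generator: manifests, methylomes and two-channel signals
# with the statistical structure the pipeline assumes (normal background,
# exponential signal, dye bias, titration/species mixtures, strain
# genotypes, tissue/age methylome structure), so every stage is testable
# without array downloads.

#' Simulation configuration
#'
#' Defaults emulate a well-performing array run: background fluorescence
#' around 500 units (s.d. 100) per channel, exponential true-signal mean
#' 5000 units, a 30% Red-channel dye surplus, and methylome effect sizes in
#' the range reported for tissue and aging methylomes (tissue marker
#' delta-beta 0.5, age drift 0.02 beta units per month).
#'
#' @param n_cg1_red,n_cg1_grn,n_cg2 CG probe counts (Infinium-I Red,
#'   Infinium-I Green, Infinium-II).
#' @param n_ch,n_snp,n_switch,n_control,n_uk CH, strain-SNP, channel-switch
#'   (human/mouse variant), control and default-masked probe counts.
#' @param mu_b,sigma_b Background mean and s.d. (pre dye bias; applied to
#'   both channels).
#' @param gain Multiplier from allele fraction x signal to fluorescence.
#' @param signal_mean Exponential mean of per-probe true signal.
#' @param dye_factor Multiplier applied to all Red-channel intensities.
#' @param n_template_molecules Template molecules for low-input mode
#'   (Inf = high input).
#' @param tissue_delta Beta offset of tissue marker probes in their tissue.
#' @param age_slope Beta drift per month at age probes.
#' @param sex_delta Beta offset of sex probes in one sex.
#' @param n_tissue_markers,n_age_probes,n_imprint Probes per structure
#'   class carved out of the CG probes.
#' @param n_branch_snps SNP probes per branch of the strain phylogeny.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cg1_red = 500, n_cg1_grn = 500, n_cg2 = 2000,
                       n_ch = 50, n_snp = 0, n_switch = 0, n_control = 20,
                       n_uk = 20,
                       mu_b = 500, sigma_b = 100, gain = 1,
                       signal_mean = 5000, dye_factor = 1.3,
                       n_template_molecules = Inf,
                       tissue_delta = 0.5, age_slope = 0.02,
                       sex_delta = 0.3,
                       n_tissue_markers = 30, n_age_probes = 30,
                       n_imprint = 20, n_branch_snps = 10) {
    cfg <- as.list(environment())
    stopifnot(mu_b > 0, sigma_b > 0, gain > 0, signal_mean > 0,
              dye_factor > 0)
    class(cfg) <- "sim_config"
    cfg
}

# Tips of the subtree below each edge of an ape phylo tree.
.edge_tips <- function(tree) {
    ntip <- length(tree$tip.label)
    desc <- vector("list", max(tree$edge))
    for (i in seq_len(ntip)) desc[[i]] <- i
    # post-order: children resolved before parents
    for (k in rev(seq_len(nrow(tree$edge)))) {
        par <- tree$edge[k, 1L]; chl <- tree$edge[k, 2L]
        desc[[par]] <- c(desc[[par]], desc[[chl]])
    }
    lapply(seq_len(nrow(tree$edge)),
           function(k) sort(unique(desc[[tree$edge[k, 2L]]])))
}

#' Simulate a probe manifest
#'
#' Builds a manifest with the configured probe counts. SNP probes carry
#' strain genotypes from a random strain phylogeny: each branch gets
#' `n_branch_snps` branch-specific SNPs whose alternate allele is shared by
#' all strains descending from that branch (clade-defining SNPs), so close
#' strains share alleles. Channel-switch probes are Infinium-I probes whose
#' design channel carries the mouse allele and whose opposite channel
#' carries the human allele. `n_uk` probes get the `uk` prefix and the
#' default mask.
#'
#' @param config A [sim_config()].
#' @param strains Character vector of strain names (>= 2) when
#'   `n_snp > 0` or `n_branch_snps` SNPs per branch are to be generated.
#' @param seed RNG seed.
#' @return A list: `manifest` (a `bm_manifest`) and `truth` (list with
#'   `genotypes` strains x SNPs matrix and the `tree` when strains given).
#' @export
simulate_manifest <- function(config = sim_config(), strains = NULL,
                              seed = 1) {
    with_seed(seed, {
        cfg <- config
        if (cfg$n_cg1_red + cfg$n_cg1_grn == 0)
            stop("need at least one Infinium-I probe (out-of-band signal ",
                 "is otherwise impossible)")
        rows <- list()
        idx <- 0L
        mk <- function(n, prefix, chem, channel, target, categories = "",
                       mask = FALSE) {
            if (n == 0) return(NULL)
            stem <- sprintf("%08d", idx + seq_len(n))
            idx <<- idx + n
            data.frame(
                probe_id = sprintf("%s%s_TC%d1", prefix, stem,
                                   ifelse(chem == "I", 1L, 2L)),
                chemistry = chem, channel = channel, target = target,
                chrom = paste0("chr", 1 + (idx + seq_len(n)) %% 19),
                pos = 1000 + 200 * (idx + seq_len(n)),
                strand = "+", categories = categories,
                mask_default = mask, stringsAsFactors = FALSE)
        }
        rows$cg1r <- mk(cfg$n_cg1_red, "cg", "I", "Red", "CG")
        rows$cg1g <- mk(cfg$n_cg1_grn, "cg", "I", "Green", "CG")
        rows$cg2 <- mk(cfg$n_cg2, "cg", "II", "Both", "CG")
        rows$ch <- mk(cfg$n_ch, "ch", "II", "Both", "CH")
        rows$uk <- mk(cfg$n_uk, "uk", "II", "Both", "CG", mask = TRUE)
        rows$ctl <- mk(cfg$n_control, "ctl", "II", "Both", "control")
        if (!is.null(rows$ctl)) rows$ctl$pos <- NA_real_
        if (cfg$n_switch > 0) {
            sw <- mk(cfg$n_switch, "cg", "I",
                     rep(c("Red", "Green"), length.out = cfg$n_switch),
                     "CG", categories = "channel_switch")
            sw$channel <- rep(c("Red", "Green"),
                              length.out = cfg$n_switch)
            sw$human_syntenic_id <- sprintf("cg%08d_TC11",
                                            9e7 + seq_len(cfg$n_switch))
            rows$sw <- sw
        }
        truth <- list()
        if (!is.null(strains)) {
            if (length(strains) < 2) stop("need >= 2 strains")
            tree <- ape::rtree(length(strains), tip.label = strains)
            tips <- .edge_tips(tree)
            n_snp_total <- nrow(tree$edge) * cfg$n_branch_snps
            G <- matrix(0, nrow = length(strains), ncol = n_snp_total,
                        dimnames = list(strains, NULL))
            for (k in seq_along(tips)) {
                cols <- (k - 1L) * cfg$n_branch_snps +
                    seq_len(cfg$n_branch_snps)
                G[tips[[k]], cols] <- 1
            }
            snp <- mk(n_snp_total, "rs", "II", "Both", "SNP")
            snp$snp_ref_allele <- "A"
            snp$snp_alt_allele <- "G"
            colnames(G) <- snp$probe_id
            gt <- as.data.frame(t(G))
            names(gt) <- paste0("genotype_", strains)
            rows$snp <- cbind(snp, gt)
            truth$genotypes <- G
            truth$tree <- tree
        } else if (cfg$n_snp > 0) {
            stop("SNP probes require a `strains` vector")
        }
        df <- do.call(rbind, c(lapply(rows, function(r) {
            if (is.null(r)) return(NULL)
            for (cn in c("human_syntenic_id", "snp_ref_allele",
                         "snp_alt_allele"))
                if (is.null(r[[cn]])) r[[cn]] <- NA_character_
            gt_all <- if (!is.null(strains))
                paste0("genotype_", strains) else character()
            for (cn in gt_all) if (is.null(r[[cn]])) r[[cn]] <- NA_real_
            r
        }), make.row.names = FALSE))
        list(manifest = manifest(df), truth = truth)
    })
}

#' Simulate true methylomes with tissue, age, sex and imprinting structure
#'
#' Baseline beta per CG/CH probe is drawn from a low/intermediate/high
#' mixture. A deterministic subset of CG probes becomes tissue markers
#' (offset by `tissue_delta` in their tissue, half hyper / half hypo), age
#' probes (linear drift `age_slope` per month, clipped to \[0, 1\]), sex
#' probes, and imprint probes (0.5 in somatic samples, polarized near 0 or
#' 1 in testis). SNP probe "beta" equals the sample strain's alternate
#' allele dosage fraction.
#'
#' @param m A `bm_manifest` from [simulate_manifest()].
#' @param annot Sample sheet data.frame: `sample`, `tissue`, `strain`,
#'   `sex`, `age` (months), `tumor` (logical), `compartment`
#'   ("somatic"/"testis"/"tumor").
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return A list: `beta` (probes x samples matrix of true beta) and
#'   `truth` (tissue marker table, age probe table, imprint/sex probe IDs).
#' @export
simulate_methylomes <- function(m, annot, config = sim_config(), seed = 1) {
    with_seed(seed, {
        cfg <- config
        n <- nrow(m); ns <- nrow(annot)
        probes <- m$probe_id
        B <- matrix(NA_real_, n, ns, dimnames = list(probes, annot$sample))
        meas <- m$target %in% c("CG", "CH")
        # baseline mixture: low / intermediate / high
        comp <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.2, 0.4))
        base <- ifelse(comp == 1, stats::rbeta(n, 2, 30),
                ifelse(comp == 2, stats::rbeta(n, 20, 20),
                       stats::rbeta(n, 30, 2)))
        B[meas, ] <- matrix(base[meas], sum(meas), ns)
        cg_plain <- which(m$target == "CG" & !has_category(m, "channel_switch") &
                          !m$mask_default)
        take <- function(k) {
            k <- min(k, length(cg_plain))
            out <- cg_plain[seq_len(k)]
            cg_plain <<- cg_plain[-seq_len(k)]
            out
        }
        tissues <- unique(annot$tissue)
        tmark <- NULL
        for (ti in tissues) {
            ids <- take(cfg$n_tissue_markers)
            if (!length(ids)) break
            dirs <- rep(c("hyper", "hypo"), length.out = length(ids))
            in_t <- annot$tissue == ti
            for (j in seq_along(ids)) {
                b0 <- if (dirs[j] == "hyper") 0.15 else 0.85
                d <- if (dirs[j] == "hyper") cfg$tissue_delta else
                    -cfg$tissue_delta
                B[ids[j], ] <- b0
                B[ids[j], in_t] <- clip01(b0 + d)
            }
            tmark <- rbind(tmark, data.frame(
                probe_id = probes[ids], tissue = ti, direction = dirs,
                stringsAsFactors = FALSE))
        }
        aids <- take(cfg$n_age_probes)
        aslope <- rep(c(1, -1), length.out = length(aids)) * cfg$age_slope
        abase <- ifelse(aslope > 0, 0.15, 0.85)
        for (j in seq_along(aids))
            B[aids[j], ] <- clip01(abase[j] + aslope[j] * annot$age)
        sids <- take(5L)
        if (length(sids) && length(unique(annot$sex)) > 1) {
            ref_sex <- sort(unique(annot$sex))[1L]
            for (j in seq_along(sids)) {
                B[sids[j], ] <- 0.2
                B[sids[j], annot$sex != ref_sex] <-
                    clip01(0.2 + cfg$sex_delta)
            }
        }
        iids <- take(cfg$n_imprint)
        if (length(iids)) {
            is_testis <- annot$compartment == "testis"
            pol <- rep(c(0.95, 0.05), length.out = length(iids))
            for (j in seq_along(iids)) {
                B[iids[j], ] <- 0.5
                B[iids[j], is_testis] <- pol[j]
            }
        }
        gt_cols <- grep("^genotype_", names(m), value = TRUE)
        snp <- which(m$target == "SNP")
        if (length(snp) && length(gt_cols)) {
            for (s in seq_len(ns)) {
                cn <- paste0("genotype_", annot$strain[s])
                if (cn %in% gt_cols) {
                    g <- as.numeric(m[[cn]][snp])
                    B[snp, s] <- ifelse(is.na(g), 0, g)
                }
            }
        }
        list(beta = B,
             truth = list(tissue_markers = tmark,
                          age_probes = data.frame(
                              probe_id = probes[aids], slope = aslope,
                              baseline = abase, stringsAsFactors = FALSE),
                          sex_probes = probes[sids],
                          imprint_probes = probes[iids]))
    })
}

# Background draws: truncated normal at 0.
.rbg <- function(n, mu, sigma) pmax(0, stats::rnorm(n, mu, sigma))

#' Simulate a two-channel signal frame from true beta values
#'
#' Per probe a true signal S ~ Exponential(`signal_mean`) is split between
#' the M and U alleles by the true beta; each measured intensity is
#' background (truncated Normal(`mu_b`, `sigma_b`)) plus `gain` x allele
#' signal. Out-of-band channels of Infinium-I probes receive background-only
#' draws, as do the unused channel slots of Infinium-II probes. All Red
#' intensities are then multiplied by `dye_factor`. Probes with NA true
#' beta (controls) get background-only signal in all slots.
#'
#' @param true_beta Named numeric vector of true beta per probe (names =
#'   probe IDs; NA allowed).
#' @param m The `bm_manifest`.
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @param signal_scale Optional per-probe multiplier on the true signal
#'   (used for species mixtures; default 1).
#' @return A [signal_frame()].
#' @export
simulate_signals <- function(true_beta, m, config = sim_config(), seed = 1,
                             signal_scale = 1) {
    with_seed(seed, {
        cfg <- config
        beta <- true_beta[m$probe_id]
        n <- nrow(m)
        scale <- rep_len(signal_scale, n)
        S <- stats::rexp(n, rate = 1 / cfg$signal_mean) * scale
        S[is.na(beta)] <- 0
        b <- ifelse(is.na(beta), 0, beta)
        sm <- cfg$gain * b * S
        su <- cfg$gain * (1 - b) * S
        MG <- .rbg(n, cfg$mu_b, cfg$sigma_b)
        UG <- .rbg(n, cfg$mu_b, cfg$sigma_b)
        MR <- .rbg(n, cfg$mu_b, cfg$sigma_b)
        UR <- .rbg(n, cfg$mu_b, cfg$sigma_b)
        i1g <- m$chemistry == "I" & m$channel == "Green"
        i1r <- m$chemistry == "I" & m$channel == "Red"
        i2 <- m$chemistry == "II"
        MG[i1g] <- MG[i1g] + sm[i1g]; UG[i1g] <- UG[i1g] + su[i1g]
        MR[i1r] <- MR[i1r] + sm[i1r]; UR[i1r] <- UR[i1r] + su[i1r]
        MG[i2] <- MG[i2] + sm[i2]; UR[i2] <- UR[i2] + su[i2]
        MR <- MR * cfg$dye_factor
        UR <- UR * cfg$dye_factor
        signal_frame(data.frame(probe_id = m$probe_id, MG = MG, UG = UG,
                                MR = MR, UR = UR,
                                stringsAsFactors = FALSE))
    })
}

#' Low-input binomial resampling of beta values
#'
#' With few template molecules, the measured methylation fraction is a
#' binomial draw over molecules: k ~ Binomial(n_molecules, beta),
#' beta' = k / n_molecules. At n = 1 intermediate beta values collapse to
#' \{0, 1\}.
#'
#' @param true_beta Numeric vector (or matrix) of beta values; NA passed
#'   through.
#' @param n_molecules Number of template molecules (>= 1).
#' @param seed RNG seed.
#' @return Resampled beta of the same shape.
#' @export
simulate_low_input <- function(true_beta, n_molecules, seed = 1) {
    if (n_molecules < 1) stop("n_molecules must be >= 1")
    with_seed(seed, {
        out <- true_beta
        ok <- !is.na(true_beta)
        out[ok] <- stats::rbinom(sum(ok), n_molecules,
                                 true_beta[ok]) / n_molecules
        out
    })
}

#' Simulate a methylation titration series
#'
#' Molecule-level mixing of a methylated and an unmethylated source at
#' known fractions: beta_mix = w * beta_meth + (1 - w) * beta_unmeth,
#' computed before signal generation.
#'
#' @param meth_beta,unmeth_beta Named true-beta vectors of the two sources.
#' @param fractions Mixing fractions in \[0, 1\] (default the 11 standard
#'   titration points, [titration_fractions()]).
#' @return Matrix probes x fractions of true mixed beta; column names are
#'   the fractions.
#' @export
simulate_titration <- function(meth_beta, unmeth_beta,
                               fractions = titration_fractions()) {
    if (any(fractions < 0 | fractions > 1))
        stop("titration fractions must lie in [0, 1]")
    out <- vapply(fractions,
                  function(w) w * meth_beta + (1 - w) * unmeth_beta,
                  numeric(length(meth_beta)))
    rownames(out) <- names(meth_beta)
    colnames(out) <- as.character(fractions)
    out
}

#' Simulate a human-mouse DNA mixture measured on both array types
#'
#' On the mouse-array view, channel-switch probes receive mouse-allele
#' signal proportional to 1 - `human_fraction` in their design channel and
#' human-allele signal proportional to `human_fraction` in the opposite
#' channel; non-syntenic mouse probes scale with the mouse fraction and
#' syntenic probes hybridize for both species. The human-array view is a
#' second manifest whose (non-syntenic) probes scale with the human
#' fraction.
#'
#' @param human_fraction Human DNA proportion in \[0, 1\].
#' @param m_mouse Mouse-array `bm_manifest` (with channel-switch probes
#'   tagged `channel_switch`).
#' @param m_human Human-array `bm_manifest`.
#' @param mouse_beta,human_beta Named true-beta vectors for the two
#'   manifests.
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return List with signal frames `mouse` and `human`.
#' @export
simulate_species_mixture <- function(human_fraction, m_mouse, m_human,
                                     mouse_beta, human_beta,
                                     config = sim_config(), seed = 1) {
    stopifnot(human_fraction >= 0, human_fraction <= 1)
    h <- human_fraction
    sw <- has_category(m_mouse, "channel_switch")
    syntenic <- !is.na(m_mouse$human_syntenic_id) & !sw
    scale_mouse <- ifelse(sw | syntenic, 1, 1 - h)
    # switch probes are handled below with a shared template signal;
    # exclude them from the base draw (background only)
    mb <- mouse_beta
    mb[m_mouse$probe_id[sw]] <- NA_real_
    sig_mouse <- simulate_signals(mb, m_mouse, config, seed = seed,
                                  signal_scale = scale_mouse)
    # switch probes: the two species' templates compete for the same
    # probe, so one signal S per probe splits h into the human (opposite)
    # channel and 1 - h into the mouse (design) channel, each divided
    # evenly between the M and U allele slots
    if (any(sw)) {
        sig_mouse <- with_seed(seed + 1L, {
            cfg <- config
            idx <- which(sw)
            S <- stats::rexp(length(idx), rate = 1 / cfg$signal_mean)
            hum <- cfg$gain * h * S / 2
            mou <- cfg$gain * (1 - h) * S / 2
            red_design <- m_mouse$channel[idx] == "Red"
            d <- cfg$dye_factor
            # red design: mouse allele in Red, human in Green
            sig_mouse$MR[idx] <- sig_mouse$MR[idx] +
                ifelse(red_design, mou, hum) * d
            sig_mouse$UR[idx] <- sig_mouse$UR[idx] +
                ifelse(red_design, mou, hum) * d
            sig_mouse$MG[idx] <- sig_mouse$MG[idx] +
                ifelse(red_design, hum, mou)
            sig_mouse$UG[idx] <- sig_mouse$UG[idx] +
                ifelse(red_design, hum, mou)
            sig_mouse
        })
    }
    sig_human <- simulate_signals(human_beta, m_human, config,
                                  seed = seed + 2L, signal_scale = h)
    list(mouse = sig_mouse, human = sig_human)
}

#' Simulate VAF observations for a strain
#'
#' Gaussian measurement noise around the genotype dosage, clipped to
#' \[0, 1\]; NA genotypes yield NA.
#'
#' @param g Genotype dosage vector in \{0, 0.5, 1, NA\}.
#' @param tau Noise s.d.
#' @param seed RNG seed.
#' @return VAF vector in \[0, 1\].
#' @export
simulate_vaf <- function(g, tau = 0.05, seed = 1) {
    with_seed(seed, {
        v <- clip01(g + stats::rnorm(length(g), 0, tau))
        v[is.na(g)] <- NA_real_
        v
    })
}

#' Simulate backcross generations
#'
#' Generation 0 is the F1 (every segregating SNP heterozygous, donor allele
#' fraction 0.5); each backcross to the recipient leaves a heterozygous SNP
#' heterozygous with probability 1/2 and otherwise fixes it
#' recipient-homozygous. SNPs are inherited independently (no linkage).
#' The expected donor allele fraction at backcross generation n is
#' 0.5^(n+1).
#'
#' @param generations Number of backcross generations after the F1 (>= 0).
#' @param n_snps Number of donor/recipient segregating SNPs.
#' @param seed RNG seed.
#' @param tau Optional Gaussian VAF noise s.d. (0 = noise-free).
#' @param include_donor Prepend the pure-donor generation (all VAF 1).
#' @return Matrix of donor-allele VAF, one row per generation
#'   ("donor" if requested, then "F1", "BC1", ...).
#' @export
simulate_backcross <- function(generations, n_snps, seed = 1, tau = 0,
                               include_donor = TRUE) {
    if (generations < 0) stop("generations must be >= 0")
    with_seed(seed, {
        rows <- list()
        if (include_donor) rows$donor <- rep(1, n_snps)
        het <- rep(TRUE, n_snps)
        rows$F1 <- rep(0.5, n_snps)
        g <- 0L
        while (g < generations) {
            g <- g + 1L
            het <- het & (stats::runif(n_snps) < 0.5)
            rows[[paste0("BC", g)]] <- ifelse(het, 0.5, 0)
        }
        V <- do.call(rbind, rows)
        if (tau > 0) V <- clip01(V + stats::rnorm(length(V), 0, tau))
        V
    })
}
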