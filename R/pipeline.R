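# 32-bit polynomial rolling hash of a deparsed R object; provenance
# stamp for outputs
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.stamp <- function(path, hash) {
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  invisible(path)
}

#' Build a pipeline run configuration
#'
#' Assembles (and lightly validates) the configuration consumed by
#' [run_pipeline()]. The configuration can also be written to / read
#' from YAML with [write_config()] / [read_config()]; it round-trips
#' through serialization unchanged.
#'
#' @param workspace directory holding the input tables (see
#'   [make_demo()] for the file conventions)
#' @param outdir output directory (created if needed)
#' @param states named list; each state is a list with `fields_MHz`,
#'   `temp_K` and optionally `tau_c_ns` (skip diffusion estimation)
#' @param stages stages to run, subset of `c("rates", "diffusion",
#'   "modelfree", "entropy", "hdx", "structure", "rdc")`
#' @param entropy_states length-2 character vector `c(free, bound)` for
#'   the entropy stage
#' @param hdx_pH,hdx_temp_K sample pH and temperature for intrinsic
#'   exchange rates (required when the hdx stage is enabled)
#' @param noe_min,sd_multiple trimming thresholds for the global
#'   correlation time
#' @param rex_ref_MHz field Rex values are referenced to
#' @param n_mc Monte Carlo resamples for model-free errors
#' @param seed integer seed governing every stochastic step
#' @param constants named overrides of [nmr_constants]
#' @return list of class `nmrdyn_config`
#' @export
pipeline_config <- function(workspace, outdir = file.path(workspace, "out"),
                            states, stages = c("rates", "diffusion",
                                               "modelfree", "entropy",
                                               "hdx"),
                            entropy_states = NULL, hdx_pH = NULL,
                            hdx_temp_K = NULL, noe_min = 0.65,
                            sd_multiple = 1, rex_ref_MHz = 800,
                            n_mc = 0, seed = 1, constants = NULL) {
  known <- c("rates", "diffusion", "modelfree", "entropy", "hdx",
             "structure", "rdc")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if ("hdx" %in% stages && (is.null(hdx_pH) || is.null(hdx_temp_K)))
    stop("the hdx stage requires hdx_pH and hdx_temp_K (no silent default)")
  if ("entropy" %in% stages && is.null(entropy_states))
    entropy_states <- names(states)[seq_len(min(2, length(states)))]
  cfg <- list(workspace = workspace, outdir = outdir, states = states,
              stages = stages, entropy_states = entropy_states,
              hdx_pH = hdx_pH, hdx_temp_K = hdx_temp_K,
              noe_min = noe_min, sd_multiple = sd_multiple,
              rex_ref_MHz = rex_ref_MHz, n_mc = n_mc, seed = seed,
              constants = constants)
  class(cfg) <- c("nmrdyn_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param cfg configuration to write
#' @param path YAML file path
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("nmrdyn_config", "list")
  cfg
}

# fit T1/T2 decay tables (one TSV, many residues) into a rate table
.fit_rate_table <- function(path) {
  tab <- read_intensity_tsv(path)
  out <- lapply(split(tab, tab$residue), function(s) {
    f <- fit_rate(s)
    data.frame(residue = s$residue[1], rate = f$rate,
               rate_err = f$rate_err, converged = f$converged,
               flat = f$flat)
  })
  do.call(rbind, out)
}

.noe_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t")
  noe <- compute_hetnoe(tab$I_sat, tab$I_unsat, tab$rms_noise)
  data.frame(residue = tab$residue, NOE = noe$NOE, NOE_err = noe$NOE_err)
}

#' Run the backbone-dynamics analysis pipeline
#'
#' Executes the enabled stages in dependency order (rates -> diffusion
#' -> model-free -> entropy; hdx independent; structure/rdc independent)
#' over the tables in `cfg$workspace`, writing one output table per
#' stage and state into `cfg$outdir`. Every output carries the
#' configuration hash; a JSON manifest records versions, seed,
#' thresholds and per-stage outputs. Fails fast on a stage error.
#'
#' Workspace file conventions (TSV): `<state>_<field>_T1.tsv`,
#' `<state>_<field>_T2.tsv` (intensity series),
#' `<state>_<field>_noe.tsv` (`residue`, `I_sat`, `I_unsat`,
#' `rms_noise`), `<state>_hdx.tsv` (build-up series),
#' `sequence.tsv` (`residue`, `aa`), `vectors.tsv` (unit N-H vectors),
#' `ensemble.pdb` (structure stage), `rdc.tsv` (`residue`,
#' `splitting_Hz`, `kappa`, `lambda`, `medium`).
#'
#' @param cfg an `nmrdyn_config` from [pipeline_config()] (or a YAML
#'   path readable by [read_config()])
#' @return invisible manifest list; side effect: files under
#'   `cfg$outdir`
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  hash <- .config_hash(unclass(cfg))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  ws <- function(...) file.path(cfg$workspace, ...)
  out <- function(...) file.path(cfg$outdir, ...)
  manifest <- list(config_hash = hash, seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("nmrdyn")),
                   thresholds = list(noe_min = cfg$noe_min,
                                     sd_multiple = cfg$sd_multiple),
                   stages = list())
  need <- function(path) {
    if (!file.exists(path)) stop("missing input: ", path)
    path
  }

  records <- list() # per state: relaxation table
  if ("rates" %in% cfg$stages) {
    for (st in names(cfg$states)) {
      s <- cfg$states[[st]]
      recs <- list()
      for (f in s$fields_MHz) {
        r1 <- .fit_rate_table(need(ws(sprintf("%s_%d_T1.tsv", st, f))))
        r2 <- .fit_rate_table(need(ws(sprintf("%s_%d_T2.tsv", st, f))))
        noe <- .noe_table(need(ws(sprintf("%s_%d_noe.tsv", st, f))))
        recs[[as.character(f)]] <- assemble_records(
          R1 = r1[, c("residue", "rate", "rate_err")],
          R2 = r2[, c("residue", "rate", "rate_err")],
          NOE = noe, field_MHz = f, temp_K = s$temp_K)
      }
      records[[st]] <- do.call(rbind, recs)
      p <- out(sprintf("%s_relaxation.tsv", st))
      write_relaxation_tsv(records[[st]], p)
      .stamp(p, hash)
      manifest$stages$rates[[st]] <- p
    }
  }

  tensors <- list()
  if ("diffusion" %in% cfg$stages) {
    for (st in names(cfg$states)) {
      s <- cfg$states[[st]]
      rec <- records[[st]]
      if (is.null(rec))
        rec <- read_relaxation_tsv(need(out(sprintf("%s_relaxation.tsv",
                                                    st))))
      fmax <- max(s$fields_MHz)
      rec1 <- rec[rec$field_MHz == fmax, , drop = FALSE]
      glob <- trim_and_average(rec1, noe_min = cfg$noe_min,
                               sd_multiple = cfg$sd_multiple,
                               constants = cfg$constants)
      diff_out <- list(tau_c_ns = glob$tau_c * 1e9,
                       tau_c_sd_ns = glob$sd * 1e9,
                       n_included = length(glob$included),
                       included = glob$included)
      if (file.exists(ws("vectors.tsv"))) {
        vec <- utils::read.delim(ws("vectors.tsv"), sep = "\t")
        # tensor from the trimmed subset only: secondary structure,
        # no large-amplitude motions
        rec_rigid <- rec1[rec1$residue %in% glob$included, , drop = FALSE]
        ax <- tryCatch(fit_axial_tensor(rec_rigid, vec,
                                        constants = cfg$constants),
                       error = function(e) NULL)
        if (!is.null(ax)) {
          diff_out$axial <- list(anisotropy = ax$anisotropy,
                                 chi2 = ax$chi2,
                                 minima = ax$minima)
        }
      }
      tensors[[st]] <- diffusion_tensor(tau_c = glob$tau_c)
      p <- out(sprintf("%s_diffusion.json", st))
      jsonlite::write_json(c(diff_out, list(config_hash = hash)), p,
                           auto_unbox = TRUE, digits = NA)
      manifest$stages$diffusion[[st]] <- p
    }
  }

  mf <- list()
  if ("modelfree" %in% cfg$stages) {
    for (st in names(cfg$states)) {
      s <- cfg$states[[st]]
      rec <- records[[st]]
      if (is.null(rec))
        rec <- read_relaxation_tsv(need(out(sprintf("%s_relaxation.tsv",
                                                    st))))
      tn <- tensors[[st]]
      if (is.null(tn)) {
        # resume from an earlier diffusion run if available
        dj <- out(sprintf("%s_diffusion.json", st))
        if (file.exists(dj)) {
          tc <- jsonlite::read_json(dj)$tau_c_ns
          tn <- diffusion_tensor(tau_c = tc * 1e-9)
        } else if (!is.null(s$tau_c_ns)) {
          tn <- diffusion_tensor(tau_c = s$tau_c_ns * 1e-9)
        } else {
          stop("modelfree stage needs the diffusion stage or tau_c_ns")
        }
      }
      mf[[st]] <- modelfree_analysis(rec, tn, n_mc = cfg$n_mc,
                                     seed = cfg$seed,
                                     rex_ref_MHz = cfg$rex_ref_MHz,
                                     constants = cfg$constants)
      tab <- mf[[st]]
      tab$te_ps <- tab$te * 1e12
      p <- out(sprintf("%s_modelfree.tsv", st))
      utils::write.table(
        tab[, c("residue", "model", "S2", "S2_err", "te_ps", "rex",
                "chi2")],
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      .stamp(p, hash)
      manifest$stages$modelfree[[st]] <- p
    }
  }

  if ("entropy" %in% cfg$stages) {
    es <- cfg$entropy_states
    read_mf <- function(st) {
      p <- out(sprintf("%s_modelfree.tsv", st))
      if (!file.exists(p)) return(NULL)
      utils::read.delim(p, sep = "\t", comment.char = "#")
    }
    a <- if (is.null(mf[[es[1]]])) read_mf(es[1]) else mf[[es[1]]]
    b <- if (is.null(mf[[es[2]]])) read_mf(es[2]) else mf[[es[2]]]
    if (is.null(a) || is.null(b))
      stop("entropy stage needs model-free results for states ",
           paste(es, collapse = " and "))
    shared <- intersect(a$residue, b$residue)
    sa <- a$S2[match(shared, a$residue)]
    sb <- b$S2[match(shared, b$residue)]
    ok <- !is.na(sa) & !is.na(sb) & sa < 1 & sb < 1
    ent <- conf_entropy(sa[ok], sb[ok],
                        temperature = cfg$states[[es[2]]]$temp_K)
    p <- out("entropy.json")
    jsonlite::write_json(
      list(free_state = es[1], bound_state = es[2], n_residues = ent$n,
           dS_J_mol_K = ent$total, TdS_kJ_mol = ent$TdS_kJ_mol,
           per_residue = data.frame(residue = shared[ok],
                                    dS = ent$per_residue),
           config_hash = hash),
      p, auto_unbox = TRUE, digits = NA)
    manifest$stages$entropy <- p
  }

  if ("hdx" %in% cfg$stages) {
    seq_tab <- utils::read.delim(need(ws("sequence.tsv")), sep = "\t")
    kint <- intrinsic_rates(seq_tab$aa, pH = cfg$hdx_pH,
                            temp_K = cfg$hdx_temp_K,
                            residues = seq_tab$residue)
    for (st in names(cfg$states)) {
      f <- ws(sprintf("%s_hdx.tsv", st))
      if (!file.exists(f)) next
      tab <- read_intensity_tsv(f)
      t1 <- min(tab$time_s)
      rows <- lapply(split(tab, tab$residue), function(s) {
        fit <- fit_buildup(s, plateau_ref = max(tab$intensity))
        data.frame(residue = s$residue[1], k_ex = fit$k_ex,
                   k_ex_err = fit$k_ex_err, category = fit$category)
      })
      hx <- do.call(rbind, rows)
      hx$k_int <- kint$k_int[match(hx$residue, kint$residue)]
      # residues without an intrinsic rate (chain start, prolines) have
      # no protection factor
      hx$category[is.na(hx$k_int) | hx$k_int <= 0] <- "no_data"
      hx$category[hx$category == "measured" &
                    (!is.finite(hx$k_ex) | hx$k_ex <= 0)] <- "no_data"
      hx$censor_bound <- ifelse(hx$category == "fast", censor_bound(t1),
                                NA_real_)
      pr <- protection(hx$k_ex, hx$k_int, hx$category)
      hx <- cbind(hx, pr[, c("P", "logP", "logP_display")])
      p <- out(sprintf("%s_hdx_protection.tsv", st))
      utils::write.table(hx, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      .stamp(p, hash)
      manifest$stages$hdx[[st]] <- p
    }
  }

  if ("structure" %in% cfg$stages) {
    ens <- read_pdb_ensemble(need(ws("ensemble.pdb")))
    sel <- select_atoms(ens, backbone = TRUE)
    ss <- superpose_stats(ens, sel)
    p <- out("structure_rmsd.json")
    jsonlite::write_json(
      list(n_models = ens$n_models, n_atoms = ss$n_atoms,
           rmsd_mean = ss$mean, rmsd_sd = ss$sd,
           per_model = ss$per_model, config_hash = hash),
      p, auto_unbox = TRUE, digits = NA)
    manifest$stages$structure <- p
  }

  if ("rdc" %in% cfg$stages) {
    tab <- utils::read.delim(need(ws("rdc.tsv")), sep = "\t")
    vec <- utils::read.delim(need(ws("vectors.tsv")), sep = "\t")
    iso <- tab[tab$medium == "isotropic", ]
    ali <- tab[tab$medium == "aligned", ]
    shared <- intersect(iso$residue, ali$residue)
    d <- rdc_from_splittings(
      ali$splitting_Hz[match(shared, ali$residue)],
      iso$splitting_Hz[match(shared, iso$residue)],
      kappa = ali$kappa[1], lambda = ali$lambda[1])
    m <- match(shared, vec$residue)
    ok <- !is.na(m)
    fit <- fit_alignment_tensor(d[ok], vec[m[ok], ])
    p <- out("rdc_tensor.json")
    jsonlite::write_json(
      list(n_rdc = sum(ok), Da = fit$Da, rhombicity = fit$rhombicity,
           Q = fit$Q, r = fit$r, eigenvalues = fit$eigenvalues,
           config_hash = hash),
      p, auto_unbox = TRUE, digits = NA)
    manifest$stages$rdc <- p
  }

  mp <- out("manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a self-contained synthetic demo workspace
#'
#' Writes a synthetic two-state (free / bound-like) dataset emulating
#' the study design - relaxation decay series at two fields, hetNOE
#' intensity pairs, a loop region that rigidifies on ligand binding,
#' H/D exchange build-up for both states with the bound form more
#' protected, a sequence table with the numbering gap, unit bond
#' vectors, a small synthetic structure ensemble and an RDC splitting
#' table - plus a matching pipeline configuration.
#'
#' @param seed integer seed; the whole workspace is deterministic in it
#' @param dir workspace directory (created); default a session tempdir
#' @param n_strand,n_loop residues per class
#' @param n_rigidified loop residues whose S2 rises on binding
#' @return list with `config`, `truths` (per-state ground truth) and
#'   `rigidified` (the seeded residue ids)
#' @export
demo_workspace <- function(seed = 1,
                           dir = file.path(tempdir(),
                                           paste0("nmrdyn_demo_", seed)),
                           n_strand = 16, n_loop = 8, n_rigidified = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  free <- gen_truth(n_strand, n_loop, seed = seed, profile = "free_58C",
                    rex_frac = 0)
  bound <- free
  bound$tensor <- diffusion_tensor(tau_c = 13.0e-9)
  # binding rigidifies a set of loop residues (a lid-like loop)
  loops <- which(free$residues$class == "loop")
  rigid <- sample(loops, min(n_rigidified, length(loops)))
  bound$residues$S2[rigid] <- pmin(free$residues$S2[rigid] + 0.15, 0.97)
  bound$residues$te[rigid] <- pmin(free$residues$te[rigid], 200e-12)
  bound$noise <- .truth_presets$bound_58C$noise
  bound$profile <- "bound_58C"
  truths <- list(free = free, bound = bound)

  fields <- c(600, 800)
  for (st in names(truths)) {
    tr <- truths[[st]]
    for (f in fields) {
      fw <- .relax_forward(tr$residues$S2, tr$residues$te,
                           tr$residues$rex, tr$tensor, 0, f)
      sig <- tr$noise[[as.character(f)]]
      for (exp_kind in c("T1", "T2")) {
        rows <- list()
        for (i in seq_len(nrow(tr$residues))) {
          rate <- if (exp_kind == "T1") fw$R1[i] else fw$R2[i]
          grid <- if (exp_kind == "T1") default_t1_grid()
                  else default_t2_grid()
          rel_noise <- 0.5 * sig[[if (exp_kind == "T1") "R1" else "R2"]] /
            rate
          rows[[i]] <- simulate_decay_series(
            rate, amplitude = 1, timepoints = grid,
            noise_sd = rel_noise, duplicate_points = grid[1],
            residue = tr$residues$residue[i],
            seed = seed + 1000L * f + 10L * i +
              (exp_kind == "T2"))
        }
        write_intensity_tsv(do.call(rbind, rows),
                            file.path(dir, sprintf("%s_%d_%s.tsv", st, f,
                                                   exp_kind)))
      }
      noe_noise <- sig[["NOE"]] / sqrt(2)
      noe_tab <- data.frame(
        residue = tr$residues$residue,
        I_sat = fw$NOE + stats::rnorm(nrow(tr$residues), 0, noe_noise),
        I_unsat = 1 + stats::rnorm(nrow(tr$residues), 0, noe_noise / 10),
        rms_noise = noe_noise)
      utils::write.table(noe_tab,
                         file.path(dir, sprintf("%s_%d_noe.tsv", st, f)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # sequence with the numbering gap; glycine at the hinge-like sites
  n <- nrow(free$residues)
  aa_pool <- c("A", "V", "L", "I", "T", "S", "N", "Q", "K", "R", "F",
               "Y", "W", "E", "D", "G", "M")
  aa <- sample(aa_pool, n, replace = TRUE)
  seq_tab <- data.frame(residue = free$residues$residue, aa = aa)
  utils::write.table(seq_tab, file.path(dir, "sequence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # H/D exchange: strand residues slow/protected, loops measurable;
  # free-form rates a constant offset faster than bound
  base_k <- ifelse(free$residues$class == "strand", 0, 1) *
    stats::runif(n, 2e-5, 8e-4)
  kex <- list(bound = base_k, free = pmin(base_k + 0.28e-3, 2.5e-3))
  for (st in names(truths)) {
    rows <- list()
    for (i in seq_len(n)) {
      k <- kex[[st]][i]
      rows[[i]] <- if (k < 1e-6)
        simulate_hdx_series(0, I0 = 1, I_inf = 0.02,
                            noise_sd = 0.002,
                            residue = seq_tab$residue[i],
                            seed = seed + 7L * i)
      else
        simulate_hdx_series(k, I0 = 1, I_inf = 0.02, noise_sd = 0.002,
                            residue = seq_tab$residue[i],
                            seed = seed + 7L * i)
    }
    write_intensity_tsv(do.call(rbind, rows),
                        file.path(dir, sprintf("%s_hdx.tsv", st)))
  }

  # unit bond vectors shared by the tensor fit and the RDC stage
  vec <- gen_bond_vectors(n, seed = seed + 3,
                          residues = free$residues$residue)
  utils::write.table(vec, file.path(dir, "vectors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # small jittered backbone ensemble (synthetic stand-in structure)
  bb <- .demo_backbone(n)
  pdb_lines <- unlist(lapply(1:5, function(m) {
    jitter <- matrix(stats::rnorm(nrow(bb$xyz) * 3, 0, 0.15), ncol = 3)
    c(sprintf("MODEL %8d", m),
      vapply(seq_len(nrow(bb$xyz)), function(i) {
        p <- bb$xyz[i, ] + jitter[i, ]
        sprintf(paste0("ATOM  %5d  %-3s %3s A%4d    ",
                       "%8.3f%8.3f%8.3f  1.00  0.00          %2s"),
                i, bb$atom[i], "ALA", bb$residue[i],
                p[1], p[2], p[3], substr(bb$atom[i], 1, 1))
      }, character(1)),
      "ENDMDL")
  }))
  writeLines(c(pdb_lines, "END"), file.path(dir, "ensemble.pdb"))

  # RDC splittings in both media from a known alignment tensor
  A <- matrix(c(6, 1.5, -0.5, 1.5, -2, 2.5, -0.5, 2.5, -4), 3, 3)
  d_true <- rdc_back_calculate(A, vec)
  J <- 93
  rdc_tab <- rbind(
    data.frame(residue = vec$residue, splitting_Hz = J / 2, kappa = 0.5,
               lambda = 0.5, medium = "isotropic"),
    data.frame(residue = vec$residue, splitting_Hz = (J + d_true) / 2,
               kappa = 0.5, lambda = 0.5, medium = "aligned"))
  utils::write.table(rdc_tab, file.path(dir, "rdc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # ground truth, for auditing recovered parameters
  for (st in names(truths)) {
    tt <- truths[[st]]$residues
    utils::write.table(tt, file.path(dir, sprintf("%s_truth.tsv", st)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfg <- pipeline_config(
    workspace = dir,
    states = list(free = list(fields_MHz = fields, temp_K = 331.15),
                  bound = list(fields_MHz = fields, temp_K = 331.15)),
    stages = c("rates", "diffusion", "modelfree", "entropy", "hdx",
               "structure", "rdc"),
    entropy_states = c("free", "bound"),
    hdx_pH = 7.0, hdx_temp_K = 331.15, seed = seed)
  write_config(cfg, file.path(dir, "config.yaml"))
  list(config = cfg, truths = truths,
       rigidified = free$residues$residue[rigid])
}

# idealized extended backbone (N, CA, C, O per residue) used for the
# synthetic demo ensemble
.demo_backbone <- function(n_res) {
  atoms <- c("N", "CA", "C", "O")
  offs <- rbind(N = c(0.0, 0.0, 0.0), CA = c(1.2, 0.9, 0.0),
                C = c(2.6, 0.6, 0.2), O = c(3.2, 1.3, 1.0))
  out <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    base <- c(3.4 * (i - 1), 1.1 * (i %% 2), 0.3 * (i %% 3))
    data.frame(residue = i, atom = atoms,
               x = offs[, 1] + base[1], y = offs[, 2] + base[2],
               z = offs[, 3] + base[3])
  }))
  list(residue = out$residue, atom = out$atom,
       xyz = as.matrix(out[, c("x", "y", "z")]))
}

#' Create, run and summarize the synthetic demo
#'
#' [demo_workspace()] followed by [run_pipeline()], with summary tables
#' in the style of a per-residue model-free figure and a
#' protection-factor figure.
#'
#' @inheritParams demo_workspace
#' @return list with `config`, `manifest`, `modelfree` (per-state
#'   tables), `delta_S2` (free vs bound), `entropy`, `hdx` tables,
#'   `rigidified` (the seeded residue ids) and `truths`
#' @export
make_demo <- function(seed = 1, dir = file.path(tempdir(),
                                                paste0("nmrdyn_demo_",
                                                       seed)),
                      n_strand = 16, n_loop = 8, n_rigidified = 4) {
  ws <- demo_workspace(seed, dir, n_strand, n_loop, n_rigidified)
  cfg <- ws$config
  manifest <- run_pipeline(cfg)

  mf_free <- utils::read.delim(file.path(cfg$outdir, "free_modelfree.tsv"),
                               sep = "\t", comment.char = "#")
  mf_bound <- utils::read.delim(file.path(cfg$outdir,
                                          "bound_modelfree.tsv"),
                                sep = "\t", comment.char = "#")
  shared <- intersect(mf_free$residue, mf_bound$residue)
  dS2 <- data.frame(
    residue = shared,
    S2_free = mf_free$S2[match(shared, mf_free$residue)],
    S2_bound = mf_bound$S2[match(shared, mf_bound$residue)])
  dS2$delta_S2 <- dS2$S2_bound - dS2$S2_free
  entropy <- jsonlite::read_json(file.path(cfg$outdir, "entropy.json"),
                                 simplifyVector = TRUE)
  hdx <- lapply(c(free = "free", bound = "bound"), function(st)
    utils::read.delim(file.path(cfg$outdir,
                                sprintf("%s_hdx_protection.tsv", st)),
                      sep = "\t", comment.char = "#"))
  list(config = cfg, manifest = manifest,
       modelfree = list(free = mf_free, bound = mf_bound),
       delta_S2 = dS2, entropy = entropy, hdx = hdx,
       rigidified = ws$rigidified,
       truths = ws$truths)
}
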