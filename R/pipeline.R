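## End-to-end orchestration from a flat INI-style run configuration:
## simulate -> assemble -> impute -> split -> clock -> transfer ->
## modules -> associate -> enrich, with a manifest of written artifacts.

#' Parse a flat INI-style configuration
#'
#' `[section]` headers followed by `key = value` lines; `#` comments and
#' blank lines ignored. Values are returned as character; numeric
#' conversion is the consumer's concern.
#'
#' @param path INI file.
#' @return named list of named character lists.
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*", "", lines))
    lines <- lines[nzchar(lines)]
    cfg <- list()
    sec <- NULL
    for (l in lines) {
        if (grepl("^\\[.*\\]$", l)) {
            sec <- gsub("^\\[|\\]$", "", l)
            cfg[[sec]] <- list()
        } else if (grepl("=", l)) {
            if (is.null(sec)) stop("key before any [section]: ", l)
            kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
            cfg[[sec]][[trimws(kv[1L])]] <- trimws(paste(kv[-1L],
                                                         collapse = "="))
        }
    }
    cfg
}

.cfgNum <- function(cfg, sec, key, default) {
    v <- cfg[[sec]][[key]]
    if (is.null(v)) default else as.numeric(v)
}

#' Run the full pipeline from a configuration file
#'
#' Executes the requested stages in dependency order on a simulated
#' cohort, logging site/sample counts at each boundary (via `message`),
#' writing per-stage TSV outputs under the configured output directory,
#' and returning (and writing) a manifest with file digests. A stage
#' whose prerequisites were not run fails with an error naming the stage.
#'
#' Supported sections/keys (all optional, with package defaults):
#' `[run] seed, out_dir, stages`; `[simulate] n_cpgs, n_rats, n_mice`;
#' `[assemble] min_coverage, min_fraction`; `[impute] k, window_bp`;
#' `[clock] components`; `[modules] deep_split, min_module_size, min_kme`.
#'
#' @param configPath INI file (see [readRunConfig()]).
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(configPath) {
    cfg <- readRunConfig(configPath)
    outDir <- cfg$run$out_dir
    if (is.null(outDir)) stop("[run] out_dir is required")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(.cfgNum(cfg, "run", "seed", 1))
    stages <- if (is.null(cfg$run$stages))
        c("simulate", "assemble", "impute", "split", "clock", "transfer",
          "modules", "associate", "enrich")
    else trimws(strsplit(cfg$run$stages, ",")[[1L]])
    state <- new.env(parent = emptyenv())
    outputs <- character(0)
    need <- function(what, stage)
        if (!exists(what, envir = state))
            stop("stage '", stage, "': missing dependency '", what,
                 "' (run its producing stage first)")
    emit <- function(name, writer) {
        p <- file.path(outDir, name)
        writer(p)
        outputs <<- c(outputs, p)
    }

    for (stage in stages) {
        message("stage: ", stage)
        switch(stage,
        simulate = {
            gc <- generatorConfig(
                seed = seed,
                nCpgs = as.integer(.cfgNum(cfg, "simulate", "n_cpgs", 20000)),
                nRats = as.integer(.cfgNum(cfg, "simulate", "n_rats", 134)),
                nMice = as.integer(.cfgNum(cfg, "simulate", "n_mice", 177)))
            state$bundle <- simulateCohort(gc)
            message("  simulated ", gc$nCpgs, " CpGs, ", gc$nRats, " rats, ",
                    gc$nMice, " mice")
        },
        assemble = {
            need("bundle", stage)
            minCov <- as.integer(.cfgNum(cfg, "assemble", "min_coverage", 10))
            minFrac <- .cfgNum(cfg, "assemble", "min_fraction", 0.8)
            rat <- samplesOf(state$bundle, "rat")
            state$ratBm <- filterSites(
                assembleMatrix(state$bundle$ratCalls, minCoverage = minCov,
                               sampleData = rat), minFraction = minFrac)
            mouse <- samplesOf(state$bundle, "mouse")
            state$mouseBm <- filterSites(
                assembleMatrix(state$bundle$mouseCalls, minCoverage = minCov,
                               sampleData = mouse), minFraction = minFrac)
            message("  rat matrix ", nrow(state$ratBm), " x ",
                    ncol(state$ratBm), "; mouse matrix ",
                    nrow(state$mouseBm), " x ", ncol(state$mouseBm))
        },
        impute = {
            need("ratBm", stage)
            k <- as.integer(.cfgNum(cfg, "impute", "k", 5))
            win <- .cfgNum(cfg, "impute", "window_bp", 3e6)
            state$ratBm <- imputeKnnWindow(state$ratBm, k = k, windowBp = win)
            state$mouseBm <- imputeKnnWindow(state$mouseBm, k = k,
                                             windowBp = win)
            emit("rat_matrix.tsv", function(p) writeBetaMatrix(state$ratBm, p))
        },
        split = {
            need("ratBm", stage)
            rat <- samplesOf(state$bundle, "rat")
            state$split <- splitByAge(rat)
            message("  train n = ", length(state$split$trainIds),
                    ", test n = ", length(state$split$testIds))
        },
        clock = {
            need("split", stage)
            rat <- samplesOf(state$bundle, "rat")
            tr <- state$split$trainIds
            bmTr <- state$ratBm[, tr]
            state$pca <- fitPCA(bmTr, nComponents = 10L)
            state$clock <- fitPCClock(state$pca, bmTr,
                                      rat[tr, "age_months"])
            pred <- predictAge(state$clock, state$ratBm)
            state$ratPred <- pred
            emit("dnam_age_rat.tsv", function(p)
                data.table::fwrite(data.table::data.table(
                    sample_id = names(pred), dnam_age = pred), p, sep = "\t"))
            te <- state$split$testIds
            message(sprintf("  test bicor = %.3f",
                            bicor(pred[te], rat[te, "age_months"])))
        },
        transfer = {
            need("clock", stage); need("mouseBm", stage)
            mapped <- liftoverSites(state$bundle$chain,
                                    intersect(siteIds(state$ratBm),
                                              names(state$bundle$ratSites)))
            pairing <- intersectMappedSites(mapped, siteIds(state$mouseBm))
            rat <- samplesOf(state$bundle, "rat")
            tr <- state$split$trainIds
            state$xfer <- transferClock(state$ratBm[, tr], rat[tr, "age_months"],
                                        pairing)
            state$pairing <- pairing
            predM <- predictAge(state$xfer, state$mouseBm)
            state$mousePred <- predM
            mouse <- samplesOf(state$bundle, "mouse")
            message(sprintf("  mouse bicor = %.3f over %d paired sites",
                            bicor(predM, mouse$age_months), nrow(pairing)))
        },
        modules = {
            need("pairing", stage)
            ds <- as.integer(.cfgNum(cfg, "modules", "deep_split", 1))
            mms <- as.integer(.cfgNum(cfg, "modules", "min_module_size", 25))
            mk <- .cfgNum(cfg, "modules", "min_kme", 0.4)
            ratX <- betaValues(state$ratBm)[state$pairing$src, ]
            mouseX <- betaValues(state$mouseBm)[state$pairing$tgt, ]
            rownames(mouseX) <- state$pairing$src
            toms <- lapply(list(ratX, mouseX), function(x)
                tomSimilarity(signedAdjacency(x, power = 1)))
            cons <- consensusTOM(toms)
            asn <- kmePrune(list(ratX, mouseX),
                            cutModules(cons, deepSplit = ds,
                                       minModuleSize = mms), minKme = mk)
            state$assignment <- asn
            emit("modules.tsv", function(p)
                data.table::fwrite(data.table::data.table(
                    site = names(moduleLabels(asn)),
                    module = moduleLabels(asn)), p, sep = "\t"))
        },
        associate = {
            need("ratPred", stage)
            rat <- samplesOf(state$bundle, "rat")
            tr <- state$split$trainIds
            ages <- stats::setNames(rat$age_months, rat$sample_id)
            ph <- pcaReduce(state$bundle$pheno, tr, ages)
            fc <- pcaReduce(state$bundle$facs, tr, ages)
            fits <- dnamAgeModels(state$ratPred[rownames(ph)],
                                  ages[rownames(ph)], ph[, 1L], fc[, 1L])
            tab <- do.call(rbind, lapply(names(fits), function(nm)
                cbind(model = nm, coefTable(fits[[nm]]))))
            state$assoc <- tab
            emit("associations.tsv", function(p)
                data.table::fwrite(tab, p, sep = "\t"))
        },
        enrich = {
            need("assignment", stage)
            lab <- moduleLabels(state$assignment)
            bg <- .parseSiteIds(names(lab))
            res <- list()
            for (m in setdiff(unique(lab), "grey")) {
                er <- regionEnrichment(names(lab)[lab == m], names(lab),
                                       state$bundle$regionSets)
                res[[m]] <- cbind(module = m, er)
            }
            tab <- do.call(rbind, res)
            emit("enrichment.tsv", function(p)
                data.table::fwrite(tab, p, sep = "\t"))
        },
        stop("unknown stage: ", stage))
    }
    manifest <- list(seed = seed, stages = stages,
                     outputs = data.frame(
                         path = outputs,
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE))
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}

#' Per-species sample table of a bundle
#'
#' @param bundle a [simulateCohort()] bundle.
#' @param species `"rat"` or `"mouse"`.
#' @return data.frame of that species' samples, keyed by sample id.
#' @export
samplesOf <- function(bundle, species) {
    df <- bundle$samples[bundle$samples$species == species, , drop = FALSE]
    rownames(df) <- df$sample_id
    df
}
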