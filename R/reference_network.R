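# The curated cardiac fibroblast reference network.
#
# Topology is assembled from the canonical fibrosis signaling literature:
# TGF-beta/Smad3 drives collagen synthesis; AngII acts through Gq/PLC/
# PKC and NADPH-oxidase ROS; IL6 through JAK/STAT; IL1 and TNF-alpha
# through TAK1/IKK/NF-kB; NE through beta-AR/cAMP/PKA/CREB; PDGF through
# RTK/Ras/ERK and PI3K/Akt; ET1 through Gq; natriuretic peptides and
# estrogen are the anti-fibrotic inputs (cGMP/PKG brake, ER-beta
# antagonism of AT1R); mechanical tension feeds integrin/FAK/Rho/ROCK
# mechanotransduction converging on MRTF/SRF and YAP. Each edge carries a
# one-line note stating its rationale.

prod_edge <- function(target, activators, note = NULL, rate = NULL) {
  e <- list(target = target, activators = activators, sign = "production")
  if (!is.null(rate)) e$rate <- rate
  if (!is.null(note)) e$note <- note
  e
}

inhib_edge <- function(target, inhibitors, note = NULL, rate = NULL) {
  e <- list(target = target, activators = inhibitors, sign = "inhibition")
  if (!is.null(rate)) e$rate <- rate
  if (!is.null(note)) e$note <- note
  e
}

#' Build the packaged reference signaling network
#'
#' Returns the curated cardiac fibroblast network: 132 intracellular
#' species organized in functional modules (10 inputs, 10 receptor
#' classes, 8 second messengers, 15 kinases/phosphatases, 12 MAPK pathway
#' components, 8 transcription-factor families, 18 mechanotransduction
#' components, 20 ECM outputs, 4 feedback precursors and 27 further
#' signaling intermediates), connected by over 200 activation and
#' inhibition edges. Four diffusible feedback fields (TGFBfb, AngIIfb,
#' IL6fb, ET1fb) are secreted from their intracellular precursors and feed
#' back onto the corresponding input species; every ECM output has a
#' matching slowly-diffusing extracellular field. Mechanical tension
#' feedback stays intracellular (tensionfb species) since it propagates
#' through cell-matrix contacts rather than diffusion.
#'
#' The same network ships as a YAML file (see [reference_network_path()])
#' so it can be inspected, edited and reloaded with [load_network()].
#'
#' @param rates optional [rate_constants()] overrides.
#' @return A validated `ecm_network`.
#' @examples
#' net <- build_reference_network()
#' network_census(net)$by_module
#' @export
build_reference_network <- function(rates = rate_constants()) {
  modules <- list(
    input = c("TGFB", "AngII", "IL6", "IL1", "TNFa", "NE", "PDGF", "ET1",
              "NP", "E2"),
    receptor = c("TGFBR", "AT1R", "IL6R", "IL1R", "TNFR", "betaAR",
                 "PDGFR", "ETAR", "NPRA", "ERb"),
    second_messenger = c("cAMP", "cGMP", "DAG", "IP3", "Ca", "ROS", "NO",
                         "PIP3"),
    kinase_phosphatase = c("PKA", "PKC", "PKG", "CamKII", "PI3K", "Akt",
                           "mTORC1", "GSK3b", "Src", "JAK", "TAK1", "PDK1",
                           "PP1", "PP2A", "calcineurin"),
    mapk = c("Ras", "Raf", "MEK1", "ERK", "MEKK1", "MKK4", "JNK", "ASK1",
             "MKK3", "p38", "MKP1", "MEK5"),
    transcription_factor = c("NFKB", "AP1", "STAT", "SRF", "NFAT", "CREB",
                             "Smad3", "YAP"),
    mechanotransduction = c("tension", "integrin", "FAK", "talin",
                            "vinculin", "paxillin", "RhoA", "ROCK", "Rac1",
                            "Cdc42", "mDia", "LIMK", "cofilin", "MLCK",
                            "MLC", "Factin", "Gactin", "MRTF"),
    ecm_precursor = c("proCI", "proCIII", "proMMP1", "proMMP2", "proMMP3",
                      "proMMP8", "proMMP9", "proMMP12", "proMMP14",
                      "TIMP1", "TIMP2", "CTGF", "periostin", "fibronectin",
                      "tenascinC", "thrombospondin4", "osteopontin",
                      "aSMA", "PAI1", "EDAFN"),
    feedback_precursor = c("TGFBfb", "AngIIfb", "IL6fb", "ET1fb"),
    other = c("BAMBI", "Smad7", "tensionfb", "Gaq", "Gas", "Gbg", "Grb2",
              "SOS", "PLCb", "PLCg", "AC", "sGC", "eNOS", "NOX", "TRAF2",
              "TRAF6", "IRAK", "MyD88", "IKK", "IkB", "mTORC2", "p70S6K",
              "eIF4E", "HIF1a", "EGR1", "Fos", "Jun"))
  species <- data.frame(
    name = unlist(modules, use.names = FALSE),
    module = rep(names(modules), lengths(modules)),
    init_lo = 0, init_hi = 0.1, stringsAsFactors = FALSE)

  p <- prod_edge; i <- inhib_edge
  edges <- list(
    # --- ligand -> receptor activation (Eq 4 production term) ---
    p("TGFBR", "TGFB", "TGF-beta binds TGFBR1/2"),
    p("AT1R", "AngII", "AngII binds AT1 receptor"),
    p("IL6R", "IL6", "IL6 binds IL6R/gp130"),
    p("IL1R", "IL1", "IL1 binds IL1R1"),
    p("TNFR", "TNFa", "TNF-alpha binds TNFR1"),
    p("betaAR", "NE", "norepinephrine binds beta-adrenergic receptor"),
    p("PDGFR", "PDGF", "PDGF binds PDGFR tyrosine kinase"),
    p("ETAR", "ET1", "endothelin-1 binds ETA receptor"),
    p("NPRA", "NP", "natriuretic peptides bind NPR-A"),
    p("ERb", "E2", "estrogen binds estrogen receptor beta"),
    # --- endogenous receptor inhibition (Eq 4 inhibition term) ---
    i("TGFBR", "BAMBI", "BAMBI pseudo-receptor blocks TGFBR"),
    i("TGFBR", "Smad7", "Smad7/Smurf targets TGFBR for degradation"),
    i("AT1R", "ERb", "ER-beta antagonizes AT1R signaling"),
    i("betaAR", "PKA", "PKA-mediated beta-AR desensitization"),
    # --- heterotrimeric G proteins and proximal transducers ---
    p("Gaq", "AT1R", "AT1R couples to Gq"),
    p("Gaq", "ETAR", "ETA receptor couples to Gq"),
    p("Gas", "betaAR", "beta-AR couples to Gs"),
    p("Gbg", "betaAR", "G-beta-gamma released on beta-AR activation"),
    p("PLCb", "Gaq", "Gq alpha subunit activates PLC-beta"),
    p("PLCb", "Gbg", "G-beta-gamma co-activates PLC-beta"),
    p("PLCg", "PDGFR", "PDGFR recruits and phosphorylates PLC-gamma"),
    p("AC", "Gas", "Gs stimulates adenylyl cyclase"),
    # --- second messengers ---
    p("cAMP", "AC", "adenylyl cyclase synthesizes cAMP"),
    p("PKA", "cAMP", "cAMP activates protein kinase A"),
    p("DAG", "PLCb", "PLC-beta cleaves PIP2 to DAG"),
    p("IP3", "PLCb", "PLC-beta cleaves PIP2 to IP3"),
    p("DAG", "PLCg", "PLC-gamma cleaves PIP2 to DAG"),
    p("IP3", "PLCg", "PLC-gamma cleaves PIP2 to IP3"),
    p("Ca", "IP3", "IP3 gates ER calcium release"),
    i("Ca", "PKG", "PKG lowers intracellular calcium"),
    p("cGMP", "NPRA", "NPR-A particulate guanylyl cyclase makes cGMP"),
    p("cGMP", "sGC", "soluble guanylyl cyclase makes cGMP"),
    p("sGC", "NO", "NO activates soluble guanylyl cyclase"),
    p("NO", "eNOS", "eNOS synthesizes NO"),
    p("eNOS", "Akt", "Akt phosphorylates and activates eNOS"),
    p("PKG", "cGMP", "cGMP activates protein kinase G"),
    p("NOX", "AT1R", "AT1R assembles NADPH oxidase"),
    p("NOX", "TNFR", "TNFR signaling activates NADPH oxidase"),
    p("NOX", "ETAR", "ET1 stimulates NADPH oxidase"),
    p("NOX", "Rac1", "Rac1 is a NADPH-oxidase subunit"),
    p("ROS", "NOX", "NADPH oxidase generates ROS"),
    # --- calcium effectors ---
    p("CamKII", "Ca", "calcium/calmodulin activates CamKII"),
    i("CamKII", "PP1", "PP1 dephosphorylates CamKII"),
    p("calcineurin", "Ca", "calcium/calmodulin activates calcineurin"),
    p("PKC", c("DAG", "Ca"), "PKC requires DAG and calcium (AND)"),
    # --- PI3K / Akt / mTOR ---
    p("PI3K", "PDGFR", "PDGFR recruits PI3K"),
    p("PI3K", "TGFBR", "non-Smad TGF-beta arm activates PI3K"),
    p("PI3K", "JAK", "IL6/JAK engages PI3K"),
    p("PI3K", "Gbg", "G-beta-gamma activates PI3K"),
    p("PI3K", "FAK", "FAK recruits PI3K at adhesions"),
    p("PIP3", "PI3K", "PI3K phosphorylates PIP2 to PIP3"),
    p("PDK1", "PIP3", "PIP3 recruits PDK1"),
    p("Akt", c("PDK1", "PIP3"), "Akt needs PDK1 and PIP3 (AND)"),
    p("Akt", "mTORC2", "mTORC2 phosphorylates Akt S473"),
    p("mTORC2", "PIP3", "PIP3 promotes mTORC2 activity"),
    p("mTORC1", "Akt", "Akt relieves TSC inhibition of mTORC1"),
    p("p70S6K", "mTORC1", "mTORC1 activates p70 S6 kinase"),
    p("eIF4E", "mTORC1", "mTORC1 releases eIF4E via 4E-BP1"),
    i("Akt", "PP2A", "PP2A dephosphorylates Akt"),
    i("GSK3b", "Akt", "Akt inhibits GSK3-beta"),
    # --- JAK / STAT ---
    p("JAK", "IL6R", "gp130 activates JAK"),
    p("STAT", "JAK", "JAK phosphorylates STAT"),
    p("STAT", "Src", "Src phosphorylates STAT"),
    # --- IL1 / TNF -> NF-kB ---
    p("MyD88", "IL1R", "IL1R recruits MyD88"),
    p("IRAK", "MyD88", "MyD88 recruits IRAK"),
    p("TRAF6", "IRAK", "IRAK engages TRAF6"),
    p("TRAF6", "IL1R", "IL1R complex recruits TRAF6 directly"),
    p("TRAF2", "TNFR", "TNFR1 recruits TRAF2"),
    p("TAK1", "TRAF6", "TRAF6 ubiquitin chains activate TAK1"),
    p("TAK1", "TRAF2", "TRAF2 activates TAK1"),
    p("TAK1", "TGFBR", "non-Smad TGF-beta arm activates TAK1"),
    p("IKK", "TAK1", "TAK1 phosphorylates IKK"),
    p("IKK", "PKC", "PKC feeds into the IKK complex"),
    i("IkB", "IKK", "IKK marks IkB for degradation"),
    p("NFKB", "IKK", "IKK releases NF-kB from IkB"),
    i("NFKB", "IkB", "IkB sequesters NF-kB"),
    i("NFKB", "PKA", "cAMP/PKA dampens NF-kB"),
    # --- MAPK: ERK branch ---
    p("Grb2", "PDGFR", "PDGFR phosphotyrosines bind Grb2"),
    p("SOS", "Grb2", "Grb2 recruits SOS"),
    i("SOS", "ERK", "ERK negative feedback on SOS"),
    p("Ras", "SOS", "SOS loads Ras with GTP"),
    p("Raf", "Ras", "Ras-GTP recruits Raf"),
    p("Raf", "PKC", "PKC activates Raf"),
    i("Raf", "PKA", "PKA inhibits Raf-1"),
    p("MEK1", "Raf", "Raf phosphorylates MEK1"),
    p("ERK", "MEK1", "MEK1 phosphorylates ERK1/2"),
    p("MEK5", "Src", "Src feeds the MEK5 branch"),
    p("ERK", "MEK5", "MEK5 branch converges on ERK activity"),
    i("ERK", "MKP1", "MKP1 dephosphorylates ERK"),
    i("ERK", "PP2A", "PP2A dephosphorylates MEK/ERK"),
    # --- MAPK: stress branches ---
    p("MEKK1", "TGFBR", "non-Smad TGF-beta arm activates MEKK1"),
    p("ASK1", "ROS", "ROS oxidizes thioredoxin, freeing ASK1"),
    p("ASK1", "TNFR", "TNFR signaling activates ASK1"),
    p("MKK3", "TAK1", "TAK1 phosphorylates MKK3"),
    p("MKK3", "ASK1", "ASK1 phosphorylates MKK3"),
    p("MKK4", "TAK1", "TAK1 phosphorylates MKK4"),
    p("MKK4", "ASK1", "ASK1 phosphorylates MKK4"),
    p("MKK4", "MEKK1", "MEKK1 phosphorylates MKK4"),
    p("p38", "MKK3", "MKK3 phosphorylates p38"),
    p("JNK", "MKK4", "MKK4 phosphorylates JNK"),
    i("p38", "MKP1", "MKP1 dephosphorylates p38"),
    i("JNK", "MKP1", "MKP1 dephosphorylates JNK"),
    p("MKP1", "ERK", "ERK induces MKP1 (negative feedback)"),
    p("MKP1", "p38", "p38 stabilizes MKP1 (negative feedback)"),
    # --- transcription factors ---
    p("Fos", "ERK", "ERK induces and activates c-Fos"),
    p("Jun", "JNK", "JNK phosphorylates c-Jun"),
    p("Jun", "ERK", "ERK supports c-Jun expression"),
    p("AP1", c("Fos", "Jun"), "AP-1 is the Fos/Jun dimer (AND)"),
    p("CREB", "PKA", "PKA phosphorylates CREB S133"),
    p("CREB", "p38", "p38/MSK phosphorylates CREB"),
    p("CREB", "CamKII", "CamKII phosphorylates CREB"),
    p("CREB", "PKG", "PKG phosphorylates CREB"),
    i("CREB", "PP1", "PP1 dephosphorylates CREB"),
    p("NFAT", "calcineurin", "calcineurin dephosphorylates/activates NFAT"),
    i("NFAT", "GSK3b", "GSK3-beta rephosphorylates NFAT"),
    p("Smad3", "TGFBR", "TGFBR phosphorylates Smad3"),
    i("Smad3", "Smad7", "Smad7 blocks Smad3 activation"),
    i("Smad3", "PKG", "cGMP/PKG antagonizes Smad3 signaling"),
    p("Smad7", "Smad3", "Smad3 induces Smad7 (negative feedback)"),
    p("BAMBI", "Smad3", "TGF-beta/Smad induces BAMBI (negative feedback)"),
    p("SRF", "MRTF", "nuclear MRTF co-activates SRF"),
    p("YAP", "RhoA", "Rho/actomyosin tension activates YAP"),
    p("EGR1", "ERK", "ERK induces EGR1"),
    p("HIF1a", "ROS", "ROS stabilizes HIF-1alpha"),
    p("HIF1a", "mTORC1", "mTORC1 boosts HIF-1alpha translation"),
    p("HIF1a", "STAT", "STAT supports HIF-1alpha expression"),
    # --- mechanotransduction ---
    # the loop-closing mechanosensing edges are attenuated (rate 0.4) so
    # the resting tension -> integrin -> FAK -> Rho -> MLC -> tension loop
    # has gain < 1 and cannot self-sustain without an external stimulus
    p("integrin", "tension", "tension engages integrins", rate = 0.4),
    p("integrin", "tensionfb", "matrix tension feedback re-engages integrins",
      rate = 0.4),
    p("FAK", "integrin", "integrin clustering activates FAK"),
    p("talin", "integrin", "integrins recruit talin"),
    p("vinculin", "talin", "talin unfolding recruits vinculin"),
    p("paxillin", "FAK", "FAK phosphorylates paxillin"),
    p("Src", "FAK", "FAK-Src adhesion complex"),
    p("Src", "AT1R", "AT1R transactivates Src"),
    p("RhoA", "FAK", "adhesion signaling activates RhoA GEFs"),
    p("RhoA", "Gaq", "Gq/G12 activate Rho GEFs"),
    i("RhoA", "PKG", "PKG inhibits RhoA"),
    i("RhoA", "PKA", "PKA inhibits RhoA"),
    i("RhoA", "Rac1", "Rac1-RhoA mutual antagonism"),
    p("ROCK", "RhoA", "RhoA-GTP activates ROCK"),
    p("mDia", "RhoA", "RhoA-GTP activates mDia formin"),
    p("LIMK", "ROCK", "ROCK phosphorylates LIMK"),
    i("cofilin", "LIMK", "LIMK inactivates cofilin"),
    p("MLCK", "Ca", "calcium/calmodulin activates MLCK"),
    p("MLC", "MLCK", "MLCK phosphorylates myosin light chain"),
    p("MLC", "ROCK", "ROCK inhibits MLC phosphatase, raising p-MLC"),
    i("MLC", "PP1", "myosin phosphatase (PP1) dephosphorylates MLC"),
    p("Rac1", "PDGFR", "PDGFR activates Rac1"),
    p("Rac1", "integrin", "integrin engagement activates Rac1"),
    p("Cdc42", "integrin", "integrin engagement activates Cdc42"),
    p("Factin", "mDia", "mDia nucleates actin polymerization"),
    i("Factin", "cofilin", "cofilin severs F-actin"),
    p("Gactin", "cofilin", "severing replenishes the G-actin pool"),
    p("MRTF", "Factin", "F-actin polymerization frees MRTF for the nucleus"),
    p("tension", c("aSMA", "Factin"),
      "alpha-SMA stress fibers generate contractile tension (AND)"),
    p("tension", "MLC", "actomyosin contraction generates tension"),
    p("tensionfb", "tension", "cell tension is stored as matrix tension"),
    # --- ECM output transcription ---
    # collagen output weights: a single pathway (Smad3 alone) reaches about
    # half-maximal synthesis; the cooperative Smad3/AP-1 gate and the
    # auxiliary activators push combinatorial stimulation toward saturation
    p("proCI", "Smad3", "Smad3 drives COL1 transcription", rate = 0.5),
    p("proCI", c("Smad3", "AP1"), "Smad3/AP-1 cooperate on COL1 (AND)"),
    p("proCI", "CTGF", "CTGF amplifies collagen I synthesis", rate = 0.3),
    p("proCI", "EGR1", "EGR1 promotes collagen I", rate = 0.2),
    p("proCI", "CREB", "beta-adrenergic CREB supports collagen I",
      rate = 0.2),
    p("proCIII", "Smad3", "Smad3 drives COL3 transcription", rate = 0.5),
    p("proCIII", c("Smad3", "AP1"), "Smad3/AP-1 cooperate on COL3 (AND)"),
    p("proCIII", "CTGF", "CTGF amplifies collagen III synthesis",
      rate = 0.3),
    p("proCIII", "CREB", "CREB supports collagen III", rate = 0.2),
    p("proMMP1", "AP1", "AP-1 drives MMP1 transcription"),
    i("proMMP1", "Smad3", "TGF-beta/Smad3 represses MMP1"),
    p("proMMP2", "Smad3", "TGF-beta induces MMP2"),
    p("proMMP2", "STAT", "IL6/STAT induces MMP2"),
    p("proMMP3", "NFKB", "NF-kB drives MMP3"),
    p("proMMP3", "AP1", "AP-1 drives MMP3"),
    p("proMMP8", "NFKB", "inflammatory NF-kB drives MMP8"),
    p("proMMP9", "NFKB", "NF-kB drives MMP9"),
    p("proMMP9", "AP1", "AP-1 drives MMP9"),
    p("proMMP12", "AP1", "AP-1 drives MMP12"),
    p("proMMP14", "Smad3", "TGF-beta induces MT1-MMP"),
    p("proMMP14", "YAP", "YAP mechanosignaling induces MT1-MMP"),
    p("TIMP1", "STAT", "IL6/STAT induces TIMP1"),
    p("TIMP1", "AP1", "AP-1 induces TIMP1"),
    p("TIMP1", "Smad3", "TGF-beta induces TIMP1"),
    p("TIMP2", "Smad3", "TGF-beta induces TIMP2"),
    p("TIMP2", "STAT", "STAT supports TIMP2"),
    p("CTGF", "Smad3", "TGF-beta/Smad3 induces CTGF"),
    p("CTGF", "YAP", "YAP/TEAD induces CTGF"),
    p("CTGF", "EGR1", "EGR1 induces CTGF"),
    p("periostin", "Smad3", "TGF-beta induces periostin"),
    p("periostin", "CREB", "adrenergic CREB induces periostin"),
    p("fibronectin", "Smad3", "TGF-beta induces fibronectin"),
    p("fibronectin", "NFKB", "NF-kB induces fibronectin"),
    p("tenascinC", "SRF", "SRF/mechanical signaling induces tenascin-C"),
    p("tenascinC", "NFKB", "inflammation induces tenascin-C"),
    p("thrombospondin4", "CREB", "adrenergic stress induces TSP-4"),
    p("osteopontin", "NFAT", "calcineurin/NFAT induces osteopontin"),
    p("osteopontin", "AP1", "AP-1 induces osteopontin"),
    p("osteopontin", "NFKB", "NF-kB induces osteopontin"),
    p("aSMA", c("SRF", "MRTF"), "MRTF/SRF drive alpha-SMA (AND)"),
    p("aSMA", "Smad3", "TGF-beta drives myofibroblast alpha-SMA"),
    p("PAI1", "Smad3", "TGF-beta induces PAI-1"),
    p("PAI1", "HIF1a", "hypoxia/HIF-1alpha induces PAI-1"),
    p("EDAFN", "Smad3", "TGF-beta drives EDA-fibronectin splicing"),
    p("EDAFN", "NFKB", "inflammation promotes EDA-fibronectin"),
    # --- secreted feedback precursors ---
    p("TGFBfb", "Smad3", "autoinduction of TGF-beta"),
    p("TGFBfb", "AP1", "AP-1 induces TGF-beta expression"),
    p("TGFBfb", "tensionfb", "mechanical stress liberates latent TGF-beta"),
    p("AngIIfb", "NFKB", "inflammation activates the local RAS"),
    p("AngIIfb", "tensionfb", "stretch triggers local AngII release"),
    p("IL6fb", "NFKB", "NF-kB drives IL6 expression"),
    p("IL6fb", "STAT", "STAT sustains IL6 expression"),
    p("ET1fb", "AP1", "AP-1 drives ET1 expression"),
    p("ET1fb", "HIF1a", "hypoxia induces ET1"),
    p("ET1fb", "NFKB", "NF-kB drives ET1 expression"))

  feedback_fields <- data.frame(
    name = c("TGFBfb", "AngIIfb", "IL6fb", "ET1fb"),
    precursor = c("TGFBfb", "AngIIfb", "IL6fb", "ET1fb"),
    target_input = c("TGFB", "AngII", "IL6", "ET1"),
    diffusion = NA_real_, clearance = NA_real_,
    stringsAsFactors = FALSE)
  ecm <- modules$ecm_precursor
  ecm_fields <- data.frame(name = ecm, precursor = ecm,
                           stringsAsFactors = FALSE)

  network_spec(species, edges, inputs = modules$input,
               feedback_fields = feedback_fields, ecm_fields = ecm_fields,
               rates = rates)
}
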