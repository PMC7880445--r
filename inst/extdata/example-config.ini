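# Example comparison configuration.
#
# universe: the reference pathways considered for reconstruction and
# comparison. This example spans the KEGG metabolic categories
# (carbohydrate, energy, lipid, nucleotide, amino-acid, glycan, cofactor,
# terpenoid, secondary-metabolite and xenobiotics metabolism) through a
# representative pathway selection; extend it to the full pathway list of
# each category for whole-metabolism comparisons.
universe = 00010,00020,00030,00040,00051,00052,00061,00071,00190,00230,00240,00250,00260,00270,00280,00330,00400,00500,00510,00520,00562,00620,00630,00640,00680,00710,00900,00910,00920,00940

# ubiquitous: compounds excluded from the shared-compound edge rule
# (water, ATP, ADP, phosphate by default).
ubiquitous = C00001,C00002,C00008,C00009

# mode: reaction collections as plain sets or multisets.
mode = set

# indexes: global indexes to report.
indexes = psim,psim_w,ssim,csim

out_dir = results
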