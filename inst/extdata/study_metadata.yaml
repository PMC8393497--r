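# Totals reported in the source study's text for the pooled voxelwise
# analysis (10-patient PET subcohort) and the stereotactic sampling.
n_voxels_high: 99773
n_voxels_low: 171877
n_biopsies_enhancing: 25
n_biopsies_nonenhancing: 54
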