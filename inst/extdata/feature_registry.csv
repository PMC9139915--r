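"feature","family"
"volume","morphology"
"morph_voxel_count","morphology"
"morph_surface_area","morphology"
"morph_surface_volume_ratio","morphology"
"morph_sphericity","morphology"
"morph_compactness1","morphology"
"morph_compactness2","morphology"
"morph_spherical_disproportion","morphology"
"morph_asphericity","morphology"
"morph_max_diameter","morphology"
"morph_major_axis","morphology"
"morph_minor_axis","morphology"
"morph_least_axis","morphology"
"morph_elongation","morphology"
"morph_flatness","morphology"
"morph_vol_density_aabb","morphology"
"morph_area_density_aabb","morphology"
"morph_vol_density_aee","morphology"
"morph_area_density_aee","morphology"
"suv_max","intensity"
"suv_mean","intensity"
"suv_peak","intensity"
"tlg","intensity"
"loc_peak_global","intensity"
"stat_min","intensity"
"stat_median","intensity"
"stat_p5","intensity"
"stat_p10","intensity"
"stat_p25","intensity"
"stat_p75","intensity"
"stat_p90","intensity"
"stat_p95","intensity"
"stat_iqr","intensity"
"stat_range","intensity"
"stat_variance","intensity"
"stat_skewness","intensity"
"stat_kurtosis","intensity"
"stat_mad","intensity"
"stat_rmad","intensity"
"stat_medad","intensity"
"stat_cov","intensity"
"stat_qcod","intensity"
"stat_energy","intensity"
"stat_rms","intensity"
"stat_com_shift","intensity"
"ivh_v10","ivh"
"ivh_v25","ivh"
"ivh_v75","ivh"
"ivh_v90","ivh"
"ivh_i10","ivh"
"ivh_i25","ivh"
"ivh_i75","ivh"
"ivh_i90","ivh"
"ivh_v10_minus_v90","ivh"
"ivh_i10_minus_i90","ivh"
"ivh_auc","ivh"
"ih_mean","histogram"
"ih_variance","histogram"
"ih_skewness","histogram"
"ih_kurtosis","histogram"
"ih_median","histogram"
"ih_min","histogram"
"ih_max","histogram"
"ih_mode","histogram"
"ih_p10","histogram"
"ih_p25","histogram"
"ih_p75","histogram"
"ih_p90","histogram"
"ih_iqr","histogram"
"ih_range","histogram"
"ih_mad","histogram"
"ih_rmad","histogram"
"ih_medad","histogram"
"ih_cov","histogram"
"ih_qcod","histogram"
"ih_entropy","histogram"
"ih_uniformity","histogram"
"ih_max_gradient","histogram"
"ih_max_gradient_level","histogram"
"ih_min_gradient","histogram"
"ih_min_gradient_level","histogram"
"glcm_joint_max","glcm"
"glcm_joint_average","glcm"
"glcm_joint_variance","glcm"
"glcm_joint_entropy","glcm"
"glcm_diff_average","glcm"
"glcm_diff_variance","glcm"
"glcm_diff_entropy","glcm"
"glcm_sum_average","glcm"
"glcm_sum_variance","glcm"
"glcm_sum_entropy","glcm"
"glcm_energy","glcm"
"glcm_contrast","glcm"
"glcm_dissimilarity","glcm"
"glcm_inv_diff","glcm"
"glcm_inv_diff_norm","glcm"
"glcm_inv_diff_mom","glcm"
"glcm_inv_diff_mom_norm","glcm"
"glcm_inv_variance","glcm"
"glcm_correlation","glcm"
"glcm_autocorrelation","glcm"
"glcm_cluster_tendency","glcm"
"glcm_cluster_shade","glcm"
"glcm_cluster_prominence","glcm"
"glcm_info_corr1","glcm"
"glcm_info_corr2","glcm"
"glrlm_sre","glrlm"
"glrlm_lre","glrlm"
"glrlm_lglre","glrlm"
"glrlm_hglre","glrlm"
"glrlm_srlgle","glrlm"
"glrlm_srhgle","glrlm"
"glrlm_lrlgle","glrlm"
"glrlm_lrhgle","glrlm"
"glrlm_glnu","glrlm"
"glrlm_glnu_norm","glrlm"
"glrlm_rlnu","glrlm"
"glrlm_rlnu_norm","glrlm"
"glrlm_run_percentage","glrlm"
"glrlm_gl_variance","glrlm"
"glrlm_rl_variance","glrlm"
"glrlm_run_entropy","glrlm"
"glszm_sze","glszm"
"glszm_lze","glszm"
"glszm_lglze","glszm"
"glszm_hglze","glszm"
"glszm_szlgle","glszm"
"glszm_szhgle","glszm"
"glszm_lzlgle","glszm"
"glszm_lzhgle","glszm"
"glszm_glnu","glszm"
"glszm_glnu_norm","glszm"
"glszm_zsnu","glszm"
"glszm_zsnu_norm","glszm"
"glszm_zone_percentage","glszm"
"glszm_gl_variance","glszm"
"glszm_zs_variance","glszm"
"glszm_zs_entropy","glszm"
"ngtdm_coarseness","ngtdm"
"ngtdm_contrast","ngtdm"
"ngtdm_busyness","ngtdm"
"ngtdm_complexity","ngtdm"
"ngtdm_strength","ngtdm"
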