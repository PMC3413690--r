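intervention,id,subcomponent_of,current_coverage_pct,target_sc1_pct,averted_sc1,target_sc2_pct,averted_sc2,target_sc3_pct,averted_sc3
Institutional delivery,institutional_delivery,,15.7,65.0,26700,90.0,45900,90.0,45900
Labor and delivery management,labor_delivery_mgmt,institutional_delivery,3.1,45.5,11800,90.0,21500,90.0,21500
Oral Rehydration Solution,ors,,37.0,65.0,26700,90.0,42600,90.0,52800
Case management of pneumonia,pneumonia_case_mgmt,,0.0,17.0,4200,90.0,20800,90.0,27000
Breastfeeding,breastfeeding,,49.0,57.0,2800,90.0,17600,90.0,18500
Case management of severe neonatal infection,neonatal_infection_mgmt,,25.0,42.0,5800,90.0,15700,90.0,20200
Antimalarials,antimalarials,,8.0,54.0,8900,90.0,12600,8.0,0
Pneumococcal vaccine,pneumococcal_vaccine,,0.0,90.0,12600,90.0,12500,0.0,0
Zinc for treatment,zinc_treatment,,0.0,62.0,9900,90.0,12000,0.0,0
Insecticide treated materials or indoor residual spraying,itn_irs,,42.0,65.0,4200,90.0,8900,42.0,0
Preventive postnatal care,postnatal_care,,5.0,25.0,2300,90.0,8700,5.0,0
Kangaroo mother care,kangaroo_care,,6.3,45.5,4800,90.0,8200,6.3,0
Prevention of Mother To Child Transmission of HIV (PMTCT),pmtct,,8.0,76.0,5700,90.0,7200,8.0,0
Improved water source,water_source,,65.2,98.3,5800,90.0,4400,90.0,0
Measles vaccine,measles_vaccine,,77.0,90.0,100,90.0,100,77.0,0
Total,total,,,,114600,,217200,,164400
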