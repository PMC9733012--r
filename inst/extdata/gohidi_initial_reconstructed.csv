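code,name,level,category,weight_percent
1,Human Health,1,none,33.33
1.1,"Reproductive, Maternal, New-born, and Child Health",2,outcome,14.28
1.1.1,Maternal Health,3,none,25.00
1.1.2,Neonatal Health,3,none,25.00
1.1.3,Child Health,3,none,25.00
1.1.4,Adolescent Fertility,3,none,25.00
1.2,Infectious Diseases,2,outcome,14.28
1.2.1,Tuberculosis,3,none,20.00
1.2.2,HIV,3,none,20.00
1.2.3,Malaria,3,none,20.00
1.2.4,Neglected Tropical Diseases,3,none,20.00
1.2.5,Hepatitis B virus,3,none,20.00
1.3,Non-communicable Diseases and Mental Health,2,outcome,14.28
1.3.1,Cardiovascular Disease,3,none,20.00
1.3.2,Neoplasms,3,none,20.00
1.3.3,Diabetes Mellitus,3,none,20.00
1.3.4,Chronic Respiratory Disease,3,none,20.00
1.3.5,Suicide,3,none,20.00
1.4,Injuries and Violence,2,outcome,14.28
1.4.1,Road Traffic,3,none,25.00
1.4.2,Unintentional Poisoning,3,none,25.00
1.4.3,Homicide,3,none,25.00
1.4.4,Physical sexual or physiological violence,3,none,25.00
1.5,Universal Health Coverage and Health Systems,2,structure,14.28
1.5.1,Health Coverage,3,none,25.00
1.5.2,Research and Development Expenditures on Health Issues,3,none,25.00
1.5.3,Domestic Health Expenditures,3,none,25.00
1.5.4,Infant Vaccination,3,none,25.00
1.6,Health Risk,2,process,14.28
1.6.1,"Unsafe or Unimproved Water, Sanitation and Hygiene",3,none,33.33
1.6.2,Household Air Pollution,3,none,33.33
1.6.3,Occupational Risks,3,none,33.33
1.7,Public Health Emergency of International: emerging infectious disease,2,process,14.28
1.7.1,Prevalence of emerging infectious disease,3,none,33.33
1.7.2,Severity of emerging infectious disease,3,none,33.33
1.7.3,Emergency response capacity,3,none,33.33
2,Animal Health,1,none,33.33
2.1,Animal Epidemic Disease,2,process,20.00
2.1.1,Diseases of Domestic Animals,3,none,50.00
2.1.2,Diseases of Wild Animals,3,none,50.00
2.2,"Animal Welfare, Relevant Regulations, and Policy Support",2,structure,20.00
2.2.1,Overexploited or Collapsed Stocks Fish,3,none,10.00
2.2.2,Trawling or Dredging Fish,3,none,10.00
2.2.3,Companion animals,3,none,10.00
2.2.4,Animals used for draught and recreation,3,none,10.00
2.2.5,Animal sentience,3,none,10.00
2.2.6,Animal protection laws,3,none,10.00
2.2.7,Laws apply to animals used in farming,3,none,10.00
2.2.8,Laws apply to animals in captivity,3,none,10.00
2.2.9,Laws apply to animals used in scientific research,3,none,10.00
2.2.10,Laws that apply to wild animals,3,none,10.00
2.3,Animal feeding,2,outcome,20.00
2.3.1,Chicken Meat Production Efficiency,3,none,25.00
2.3.2,Pig Meat Production Efficiency,3,none,25.00
2.3.3,Cattle Production Efficiency,3,none,25.00
2.3.4,Cattle Milk Production Efficiency,3,none,25.00
2.4,Animal Biodiversity,2,outcome,20.00
2.4.1,Endemic Mammal Species,3,none,11.11
2.4.2,Endemic Bird Species,3,none,11.11
2.4.3,Endemic Amphibian Species,3,none,11.11
2.4.4,Endemic Reef-forming Coral Species,3,none,11.11
2.4.5,Endemic Freshwater Crab Species,3,none,11.11
2.4.6,Endemic Shark and Ray Species,3,none,11.11
2.4.7,Threatened Mammal Species,3,none,11.11
2.4.8,Threatened Bird Species,3,none,11.11
2.4.9,Threatened Fish Species,3,none,11.11
2.5,Fisheries,2,outcome,20.00
2.5.1,Discarded Fish,3,none,100.00
3,Environmental Health,1,none,33.33
3.1,Air Quality,2,outcome,14.28
3.1.1,Ambient Particulate Matter Pollution,3,none,33.33
3.1.2,Household Solid Fuels,3,none,33.33
3.1.3,Ambient Ozone Pollution,3,none,33.33
3.2,Climate Change,2,outcome,14.28
3.2.1,Climate Risk,3,none,50.00
3.2.2,Greenhouse Gas,3,none,50.00
3.3,Ecosystem Services,2,outcome,14.28
3.3.1,Area at Risk Elevation,3,none,20.00
3.3.2,Tree Cover Loss,3,none,20.00
3.3.3,Grassland Loss,3,none,20.00
3.3.4,Wetland Loss,3,none,20.00
3.3.5,Mineral Depletion,3,none,20.00
3.4,Sanitation and Water Resources,2,outcome,14.28
3.4.1,Freshwater,3,none,33.33
3.4.2,Clean Drinking Water,3,none,33.33
3.4.3,Renewable Internal Freshwater Resources,3,none,33.33
3.5,Waste management,2,outcome,14.28
3.5.1,Fertilizer Consumption,3,none,14.28
3.5.2,Controlled Solid Waste,3,none,14.28
3.5.3,SO2 Growth,3,none,14.28
3.5.4,NOX Growth,3,none,14.28
3.5.5,Wastewater Treatment,3,none,14.28
3.5.6,Electronic Waste,3,none,14.28
3.5.7,Non-recycled Municipal Solid Waste,3,none,14.28
3.6,Environmental Biodiversity,2,outcome,14.28
3.6.1,Protected Areas Representativeness,3,none,25.00
3.6.2,Species Habitat,3,none,25.00
3.6.3,Biodiversity Habitat,3,none,25.00
3.6.4,Threatened Plant Species,3,none,25.00
3.7,Marine life,2,outcome,14.28
3.7.1,Marine Protected Areas,3,none,100.00
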