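id,dimension,label,description
A1,functional,Minimalist emergency call,Entity big button
A2,functional,Basic vital signs monitoring,Simple blood pressure heart rate and blood oxygen detection equipment
A3,functional,Clear guidance system,Guides the user through the whole process from calling to using the equipment
A4,functional,Barrier-free and safe space,Room for wheelchairs to turn around; no sharp corners
A5,functional,Identity recognition and intelligent early warning,Card-based identification with automatic medical-history retrieval and abnormal-reading alerts
B1,appearance,Eye-catching visual design,Large illuminated sign
B2,appearance,Safe and comfortable materials,Eco-friendly gentle non-slip antibacterial materials
B3,appearance,Integrated functional layout,Detection equipment seats information screens and supply cabinets in one unified system
B4,appearance,Elder-friendly user interface,Minimalist design with oversized fonts high-contrast icons and clear touch areas
C1,culture_management,Personalized health services,Users or family members customize health focus areas on the platform
C2,culture_management,Community health platform integration,Family-doctor system and regional health cloud platform connected with authorized data sync
C3,culture_management,Environmental adaptation design,Good insulation ventilation and drainage performance
C4,culture_management,Easy to maintain and manage,Modular design
C5,culture_management,Promote community sharing and belonging,Community-culture elements and a community health bulletin board
D1,technical,System intelligent integration,Complete monitoring-warning-response closed loop
D2,technical,Reliability and stability,Remote fault diagnosis capabilities
D3,technical,Information visualization and minimalist operations,One interface one main task with reserved interfaces for future features
D4,technical,Modularity and scalability,Reserved software and hardware interfaces for future expansion
D5,technical,Strict data privacy and security,All health data encrypted in transmission and storage
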