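country,code,maddison_cluster,cultural_cluster,weird
South Africa,ZA,African,African,FALSE
Egypt,EG,African,African,FALSE
Czech Republic,CZ,East Europe,East Europe,FALSE
Hungary,HU,East Europe,East Europe,FALSE
Poland,PL,East Europe,East Europe,FALSE
Romania,RO,East Europe,East Europe,FALSE
Russia,RU,East Europe,East Europe,FALSE
Slovakia,SK,East Europe,East Europe,FALSE
Ukraine,UA,East Europe,East Europe,FALSE
Albania,AL,East Europe,East Europe,FALSE
Serbia,RS,East Europe,East Europe,FALSE
Croatia,HR,East Europe,East Europe,FALSE
Macedonia,MK,East Europe,East Europe,FALSE
Cyprus,CY,East Europe,East Europe,FALSE
Germany,DE,Western Europe,Germanic,TRUE
Austria,AT,Western Europe,Germanic,TRUE
Switzerland,CH,Western Europe,Germanic,TRUE
England,GB,Western Europe,Anglo,TRUE
Ireland,IE,Western Europe,Anglo,TRUE
Sweden,SE,Western Europe,Nordic,TRUE
Norway,NO,Western Europe,Nordic,TRUE
Finland,FI,Western Europe,Nordic,TRUE
Denmark,DK,Western Europe,Nordic,TRUE
Netherlands,NL,Western Europe,Nordic,TRUE
France,FR,Western Europe,Latin Europe,TRUE
Belgium,BE,Western Europe,Latin Europe,TRUE
Italy,IT,Western Europe,Latin Europe,TRUE
Portugal,PT,Western Europe,Latin Europe,TRUE
Spain,ES,Western Europe,Latin Europe,TRUE
Greece,GR,Western Europe,Near East,TRUE
United Arab Emirates,AE,Western Asia,Arabic,FALSE
Saudi Arabia,SA,Western Asia,Arabic,FALSE
Turkey,TR,Western Asia,Near East,FALSE
Israel,IL,Western Asia,Latin Europe,FALSE
Lebanon,LB,Western Asia,Near East,FALSE
Iran,IR,Western Asia,Near East,FALSE
United States,US,Western Offshoot,Anglo,TRUE
Canada,CA,Western Offshoot,Anglo,TRUE
Australia,AU,Western Offshoot,Anglo,TRUE
New Zealand,NZ,Western Offshoot,Anglo,TRUE
Argentina,AR,Latin America,Latin America,FALSE
Peru,PE,Latin America,Latin America,FALSE
Chile,CL,Latin America,Latin America,FALSE
Bolivia,BO,Latin America,Latin America,FALSE
Colombia,CO,Latin America,Latin America,FALSE
Puerto Rico,PR,Latin America,Latin America,FALSE
Ecuador,EC,Latin America,Latin America,FALSE
Costa Rica,CR,Latin America,Latin America,FALSE
Venezuela,VE,Latin America,Latin America,FALSE
Uruguay,UY,Latin America,Latin America,FALSE
Brasil,BR,Latin America,Latin America,FALSE
Mexico,MX,Latin America,Latin America,FALSE
India,IN,East Asia,Far East,FALSE
Indonesia,ID,East Asia,Far East,FALSE
Malaysia,MY,East Asia,Far East,FALSE
Philippines,PH,East Asia,Far East,FALSE
Thailand,TH,East Asia,Far East,FALSE
Vietnam,VN,East Asia,Far East,FALSE
China,CN,East Asia,Confucian Asia,FALSE
Singapore,SG,East Asia,Confucian Asia,FALSE
Hong Kong,HK,East Asia,Confucian Asia,FALSE
Taiwan,TW,East Asia,Confucian Asia,FALSE
Japan,JP,East Asia,Confucian Asia,FALSE
South Korea,KR,East Asia,Confucian Asia,FALSE
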